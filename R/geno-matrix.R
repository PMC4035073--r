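#' Genotype matrix for inbred cultivar panels
#'
#' `geno_matrix()` bundles diploid SNP calls for a set of essentially inbred
#' cultivars with the marker map they were scored on. Calls are stored as
#' alternate-allele dosages: `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate), `NA` (missing). The marker map is kept sorted
#' by chromosome and strictly increasing physical position so that
#' window-based scans and adjacent-pair LD are well defined.
#'
#' @param calls Integer matrix, cultivars in rows and markers in columns,
#'   values in `{0, 1, 2, NA}`. Column names must match `markers$marker_id`;
#'   row names (or `cultivar_ids`) name the cultivars.
#' @param markers Tibble with columns `marker_id`, `chromosome`,
#'   `position_bp` (1-based), `ref`, `alt`.
#' @param cultivar_ids Character vector of cultivar names; defaults to
#'   `rownames(calls)`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, markers, cultivar_ids = rownames(calls)) {
  markers <- as_tibble(markers)
  required <- c("marker_id", "chromosome", "position_bp", "ref", "alt")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    abort(paste0("marker map lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(markers$marker_id)) {
    dup <- unique(markers$marker_id[duplicated(markers$marker_id)])
    abort(paste0("duplicate marker_id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (is.null(cultivar_ids)) abort("cultivar_ids required (or rownames on `calls`)")
  if (anyDuplicated(cultivar_ids)) abort("duplicate cultivar ids")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(cultivar_ids) || ncol(calls) != nrow(markers)) {
    abort(sprintf(
      "calls is %d x %d but there are %d cultivars and %d markers",
      nrow(calls), ncol(calls), length(cultivar_ids), nrow(markers)
    ))
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("calls must be dosages in {0, 1, 2} or NA")
  }
  if (!is.null(colnames(calls)) && !identical(colnames(calls), markers$marker_id)) {
    calls <- calls[, markers$marker_id, drop = FALSE]
  }
  markers <- mutate(markers,
    marker_id = as.character(.data$marker_id),
    chromosome = as.character(.data$chromosome),
    position_bp = as.integer(.data$position_bp),
    ref = as.character(.data$ref), alt = as.character(.data$alt)
  )
  ord <- sort_markers(mutate(markers, .idx = row_number()))
  not_increasing <- ord |>
    group_by(.data$chromosome) |>
    summarise(ok = all(diff(.data$position_bp) > 0), .groups = "drop")
  if (!all(not_increasing$ok)) {
    abort(paste0(
      "positions must be strictly increasing within chromosome(s): ",
      paste(not_increasing$chromosome[!not_increasing$ok], collapse = ", ")
    ))
  }
  calls <- calls[, ord$.idx, drop = FALSE]
  markers <- select(ord, -".idx")
  dimnames(calls) <- list(cultivar_ids, markers$marker_id)
  structure(
    list(calls = calls, markers = markers, cultivar_ids = cultivar_ids),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_chr <- length(unique(x$markers$chromosome))
  miss <- mean(is.na(x$calls))
  cat(sprintf(
    "<geno_matrix> %d cultivars x %d markers on %d chromosome(s); %.1f%% missing\n",
    length(x$cultivar_ids), nrow(x$markers), n_chr, 100 * miss
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Marker map of a genotype matrix
#' @param geno A [geno_matrix()].
#' @return Tibble with one row per marker.
#' @export
marker_map <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  geno$markers
}

#' Cultivar ids of a genotype matrix
#' @param geno A [geno_matrix()].
#' @return Character vector.
#' @export
cultivars <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  geno$cultivar_ids
}

#' Alternate-allele dosage matrix
#' @param geno A [geno_matrix()].
#' @param cultivar_ids,marker_ids Optional subsets.
#' @return Integer matrix (cultivars x markers) of dosages 0/1/2 with NA
#'   for missing calls.
#' @export
dosage <- function(geno, cultivar_ids = NULL, marker_ids = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  m <- geno$calls
  if (!is.null(cultivar_ids)) {
    unknown <- setdiff(cultivar_ids, rownames(m))
    if (length(unknown)) abort(paste0("unknown cultivar(s): ", paste(head(unknown, 5), collapse = ", ")))
    m <- m[cultivar_ids, , drop = FALSE]
  }
  if (!is.null(marker_ids)) {
    unknown <- setdiff(marker_ids, colnames(m))
    if (length(unknown)) abort(paste0("unknown marker(s): ", paste(head(unknown, 5), collapse = ", ")))
    m <- m[, marker_ids, drop = FALSE]
  }
  m
}

#' Subset a genotype matrix
#'
#' @param geno A [geno_matrix()].
#' @param cultivar_ids,marker_ids Ids to keep (default: all). Marker order is
#'   always re-normalised to map order.
#' @return A [geno_matrix()].
#' @export
geno_subset <- function(geno, cultivar_ids = NULL, marker_ids = NULL) {
  m <- dosage(geno, cultivar_ids, marker_ids)
  km <- filter(geno$markers, .data$marker_id %in% colnames(m))
  geno_matrix(m[, km$marker_id, drop = FALSE], km, rownames(m))
}

#' Tidy view of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return Long tibble with `cultivar_id`, `marker_id`, `chromosome`,
#'   `position_bp` and `call` (`HOM_REF`/`HET`/`HOM_ALT`/`NA`).
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  long <- as_tibble(x$calls, rownames = "cultivar_id") |>
    pivot_longer(-"cultivar_id", names_to = "marker_id", values_to = "dosage")
  long |>
    left_join(select(x$markers, "marker_id", "chromosome", "position_bp"),
      by = "marker_id"
    ) |>
    mutate(call = c("HOM_REF", "HET", "HOM_ALT")[.data$dosage + 1L]) |>
    select("cultivar_id", "marker_id", "chromosome", "position_bp", "dosage", "call")
}
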