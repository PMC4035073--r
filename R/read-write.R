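#' Read genotypes from the tab-separated marker table
#'
#' The dialect has one row per marker with header
#' `marker_id chromosome position_bp ref alt <cultivar ...>`; calls are coded
#' `A`/`C`/`G`/`T` (homozygote for that base), `H` (heterozygote) and `N`
#' (missing). A call letter must equal the marker's `ref` or `alt` base.
#'
#' @param path Path to the tab-separated file.
#' @return A [geno_matrix()]; markers are sorted by chromosome and position.
#' @export
read_genotypes_tabular <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  fixed <- c("marker_id", "chromosome", "position_bp", "ref", "alt")
  if (!identical(names(tab)[seq_along(fixed)], fixed)) {
    abort(paste0("genotype table must start with columns: ",
                 paste(fixed, collapse = ", ")))
  }
  cvs <- setdiff(names(tab), fixed)
  if (!length(cvs)) abort("genotype table has no cultivar columns")
  if (anyDuplicated(tab$marker_id)) {
    i <- which(duplicated(tab$marker_id))[1]
    abort(sprintf("line %d: duplicate marker '%s'", i + 1L, tab$marker_id[i]))
  }
  pos <- suppressWarnings(as.integer(tab$position_bp))
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1]
    abort(sprintf("line %d: malformed position_bp '%s'", i + 1L, tab$position_bp[i]))
  }
  calls <- matrix(NA_integer_, nrow = length(cvs), ncol = nrow(tab),
                  dimnames = list(cvs, tab$marker_id))
  for (j in seq_len(nrow(tab))) {
    cc <- toupper(as.character(tab[j, cvs]))
    ref <- toupper(tab$ref[j]); alt <- toupper(tab$alt[j])
    dos <- rep(NA_integer_, length(cc))
    dos[cc == ref] <- 0L
    dos[cc == alt] <- 2L
    dos[cc == "H"] <- 1L
    unknown <- !(cc %in% c(ref, alt, "H", "N")) & !is.na(cc)
    if (any(unknown)) {
      abort(sprintf("line %d: unknown allele symbol '%s' for marker '%s' (ref=%s, alt=%s)",
                    j + 1L, cc[which(unknown)[1]], tab$marker_id[j], ref, alt))
    }
    calls[, j] <- dos
  }
  markers <- tibble(marker_id = tab$marker_id, chromosome = tab$chromosome,
                    position_bp = pos, ref = toupper(tab$ref), alt = toupper(tab$alt))
  geno_matrix(calls, markers, cvs)
}

#' Write genotypes in the tab-separated marker dialect
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tabular <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  mk <- geno$markers
  code <- vapply(seq_len(nrow(mk)), function(j) {
    d <- geno$calls[, j]
    out <- rep("N", length(d))
    out[!is.na(d) & d == 0L] <- mk$ref[j]
    out[!is.na(d) & d == 2L] <- mk$alt[j]
    out[!is.na(d) & d == 1L] <- "H"
    paste(out, collapse = "\t")
  }, character(1))
  header <- paste(c("marker_id", "chromosome", "position_bp", "ref", "alt",
                    geno$cultivar_ids), collapse = "\t")
  body <- paste(mk$marker_id, mk$chromosome, mk$position_bp, mk$ref, mk$alt,
                code, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Only the `GT` field is used: `0/0` maps to homozygous reference, `1/1`
#' to homozygous alternate, `0/1` or `1/0` to heterozygous, `./.` to
#' missing. Phased separators (`|`) are accepted. Multi-allelic records are
#' rejected.
#'
#' @param path Path to a VCF (v4.x, plain text or gzipped).
#' @return A [geno_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fx$ALT, fixed = TRUE))) {
    bad <- fx$ID[grepl(",", fx$ALT, fixed = TRUE)]
    abort(paste0("multi-allelic VCF record(s) not supported: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (!"gt" %in% slotNames(v) || ncol(v@gt) < 2) abort("VCF has no sample genotypes")
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    abort("VCF FORMAT lacks GT field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% "0/0"] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt %in% "1/1"] <- 2L
  unknown <- !is.na(gt) & !(gt %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown)) {
    abort(paste0("unsupported GT value(s): ",
                 paste(head(unique(gt[unknown]), 5), collapse = ", ")))
  }
  ids <- fx$ID
  if (anyNA(ids) || any(ids == ".")) {
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fx$CHROM, "_", fx$POS), ids)
  }
  markers <- tibble(marker_id = ids, chromosome = fx$CHROM,
                    position_bp = as.integer(fx$POS),
                    ref = toupper(fx$REF), alt = toupper(fx$ALT))
  geno_matrix(t(dos), markers, colnames(gt))
}

panel_groups <- c("HY", "PD", "PO_INDICA", "PO_OTHER",
                  "REF_INDICA", "REF_JAPONICA", "OTHER")

#' Read a population panel
#'
#' Two-column CSV `cultivar_id,group` assigning each cultivar to one of the
#' analysis groups `HY` (high-yielding), `PD` (domestic japonica parents),
#' `PO_INDICA` (overseas indica parents), `PO_OTHER`, `REF_INDICA`,
#' `REF_JAPONICA` or `OTHER`.
#'
#' @param path CSV path.
#' @param geno Optional [geno_matrix()]; panel entries absent from it
#'   trigger a warning listing the ids.
#' @return Tibble `cultivar_id`, `group`.
#' @export
read_panel <- function(path, geno = NULL) {
  p <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("cultivar_id", "group") %in% names(p))) {
    abort("panel must have columns cultivar_id,group")
  }
  p <- select(p, "cultivar_id", "group")
  if (anyDuplicated(p$cultivar_id)) {
    dup <- unique(p$cultivar_id[duplicated(p$cultivar_id)])
    abort(paste0("cultivar(s) listed twice in panel: ", paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(p$group), panel_groups)
  if (length(bad)) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", "),
                 "; expected one of ", paste(panel_groups, collapse = ", ")))
  }
  if (!is.null(geno)) {
    absent <- setdiff(p$cultivar_id, cultivars(geno))
    if (length(absent)) {
      warn(paste0("panel cultivar(s) absent from genotypes: ",
                  paste(absent, collapse = ", ")))
    }
  }
  p
}

#' @rdname read_panel
#' @param panel Tibble as returned by `read_panel()`.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel[, c("cultivar_id", "group")], path)
  invisible(path)
}

#' Read a wide phenotype CSV into a long table
#'
#' First column is `cultivar_id`; every other column is one trait. Empty
#' cells become missing values (never zero).
#'
#' @param path CSV path.
#' @return Long tibble `cultivar_id`, `trait`, `value`.
#' @export
read_phenotypes <- function(path) {
  w <- readr::read_csv(path, col_types = readr::cols(
    cultivar_id = "c", .default = "d"), progress = FALSE)
  if (names(w)[1] != "cultivar_id") abort("first phenotype column must be cultivar_id")
  long <- pivot_longer(w, -"cultivar_id", names_to = "trait", values_to = "value")
  if (anyDuplicated(long[, c("cultivar_id", "trait")])) {
    abort("duplicate (cultivar, trait) pairs in phenotype file")
  }
  long
}

#' @rdname read_phenotypes
#' @param pheno Long tibble `cultivar_id`, `trait`, `value`.
#' @export
write_phenotypes <- function(pheno, path) {
  wide <- pivot_wider(pheno, names_from = "trait", values_from = "value")
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Read a candidate-feature catalog (genes and QTLs)
#'
#' Accepts either a 6-column BED (`chrom start end name kind trait_category`,
#' 0-based half-open; converted to 1-based inclusive internally) or a CSV
#' with header `feature_id,feature_kind,chromosome,start_bp,end_bp,
#' trait_category` already in 1-based inclusive coordinates. `feature_kind`
#' is `GENE` or `QTL`.
#'
#' @param path File path; `.bed` selects the BED reader, anything else the CSV
#'   reader.
#' @return Tibble `feature_id`, `feature_kind`, `chromosome`, `start_bp`,
#'   `end_bp`, `trait_category` (1-based inclusive).
#' @export
read_features <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    b <- readr::read_tsv(path, col_names = c("chromosome", "start", "end",
                                             "feature_id", "feature_kind",
                                             "trait_category"),
                         col_types = "ciiccc", progress = FALSE)
    if (any(b$start > b$end)) {
      bad <- which(b$start > b$end)[1]
      abort(sprintf("BED line %d: start %d > end %d", bad, b$start[bad], b$end[bad]))
    }
    feats <- tibble(feature_id = b$feature_id, feature_kind = b$feature_kind,
                    chromosome = b$chromosome,
                    start_bp = bed_to_internal(b$start, b$end)$start_bp,
                    end_bp = bed_to_internal(b$start, b$end)$end_bp,
                    trait_category = b$trait_category)
  } else {
    feats <- readr::read_csv(path, col_types = readr::cols(
      feature_id = "c", feature_kind = "c", chromosome = "c",
      start_bp = "i", end_bp = "i", trait_category = "c"), progress = FALSE)
  }
  bad_kind <- setdiff(unique(feats$feature_kind), c("GENE", "QTL"))
  if (length(bad_kind)) {
    abort(paste0("feature_kind must be GENE or QTL; found: ",
                 paste(bad_kind, collapse = ", ")))
  }
  if (any(feats$start_bp > feats$end_bp)) abort("feature with start_bp > end_bp")
  feats
}

#' @rdname read_features
#' @param features Tibble as returned by `read_features()`.
#' @export
write_features_bed <- function(features, path) {
  co <- internal_to_bed(features$start_bp, features$end_bp)
  writeLines(paste(features$chromosome, co$start, co$end, features$feature_id,
                   features$feature_kind, features$trait_category, sep = "\t"),
             path)
  invisible(path)
}

#' Convert between BED (0-based half-open) and internal (1-based inclusive)
#' interval coordinates
#'
#' @param start,end BED coordinates.
#' @return `bed_to_internal()`: list with `start_bp`, `end_bp`;
#'   `internal_to_bed()`: list with `start`, `end`.
#' @export
bed_to_internal <- function(start, end) {
  if (any(start > end)) abort("BED start > end")
  list(start_bp = as.integer(start + 1L), end_bp = as.integer(end))
}

#' @rdname bed_to_internal
#' @param start_bp,end_bp Internal 1-based inclusive coordinates.
#' @export
internal_to_bed <- function(start_bp, end_bp) {
  list(start = as.integer(start_bp - 1L), end = as.integer(end_bp))
}
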