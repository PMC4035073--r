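# shared internal helpers

# Numeric-aware ordering of chromosome labels: "chr2" < "chr10", plain
# integers sort numerically, anything else falls back to lexicographic.
chrom_order <- function(x) {
  ux <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(gsub("^[Cc]hr", "", ux)))
  ord <- order(is.na(num), num, ux)
  factor(as.character(x), levels = ux[ord])
}

# Sort a marker tibble by chromosome (numeric-aware) then position.
sort_markers <- function(markers) {
  markers |>
    mutate(.chrom_f = chrom_order(.data$chromosome)) |>
    arrange(.data$.chrom_f, .data$position_bp) |>
    select(-".chrom_f")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Draw without replacement using R's RNG; isolates seed handling so every
# stochastic entry point can take `seed` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
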