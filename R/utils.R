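# internal helpers shared across modules

# run `expr` under a local RNG state seeded with `seed`; restores .Random.seed
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

stop_idpnmr <- function(..., class = "idpnmr_error") {
  abort(paste0(...), class = class)
}

check_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_idpnmr("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) {
    stop_idpnmr("`", name, "` must be positive")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_idpnmr("`", name, "` must be a whole number")
  }
  invisible(x)
}

# residue interval helpers; `region` is c(first, last) or "all"
region_filter <- function(residue_number, region) {
  if (identical(region, "all")) {
    return(rep(TRUE, length(residue_number)))
  }
  if (!is.numeric(region) || length(region) != 2L || region[2] < region[1]) {
    stop_idpnmr("`region` must be \"all\" or c(first, last) with first <= last")
  }
  residue_number >= region[1] & residue_number <= region[2]
}
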