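#' Convert concentrations to molar
#'
#' Assay tables carry an explicit unit column; all internal computation is
#' in molar. Accepted units: `"M"`, `"mM"`, `"uM"` (or `"µM"`),
#' `"nM"`, `"pM"`.
#'
#' @param x numeric vector of concentrations.
#' @param unit character scalar or vector of units, recycled against `x`.
#' @return numeric vector in molar.
#' @examples
#' to_molar(c(3, 10, 30), "uM")
#' @export
to_molar <- function(x, unit) {
  stopifnot(is.numeric(x))
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6,
             nM = 1e-9, pM = 1e-12)
  u <- as.character(unit)
  bad <- !(u %in% names(scale))
  if (any(bad)) {
    stop("unknown concentration unit(s): ",
         paste(unique(u[bad]), collapse = ", "))
  }
  x * unname(scale[u])
}

# restore-on-exit seeded evaluation; keeps generator calls from disturbing
# the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
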