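#' Drive-model control parameters
#'
#' Bundles the three control parameters of the deterministic X-linked drive
#' model and validates their domains.
#'
#' @param t Drive strength: the fraction of functional X-bearing sperm
#'   produced by driver males. `t = 0.5` is the Mendelian control; the drive
#'   domain proper is `0.5 < t <= 1`.
#' @param z Reproduction index: offspring produced per reproducing female per
#'   generation. The model requires `z >= 2`, otherwise the population
#'   declines even without a driver.
#' @param w Mating index: number of females a single male can fertilize.
#'   `w >= 2`; this parameter sets when males become limiting.
#'
#' @return An object of class `drive_params`: a named list with elements
#'   `t`, `z` and `w`.
#' @examples
#' drive_params(t = 0.75, z = 2, w = 2)
#' @export
drive_params <- function(t, z = 2, w = 2) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t),
            is.numeric(z), length(z) == 1L, is.finite(z),
            is.numeric(w), length(w) == 1L, is.finite(w))
  if (t < 0.5 || t > 1)
    stop("drive strength `t` must lie in [0.5, 1] (t = 0.5 is the Mendelian control)")
  if (z < 2)
    stop("reproduction index `z` must be >= 2")
  if (w < 2)
    stop("mating index `w` must be >= 2")
  structure(list(t = t, z = z, w = w), class = "drive_params")
}

#' @export
print.drive_params <- function(x, ...) {
  cat(sprintf("X-linked drive parameters: t = %g, z = %g, w = %g\n",
              x$t, x$z, x$w))
  invisible(x)
}

as_drive_params <- function(x) {
  if (inherits(x, "drive_params")) return(x)
  if (is.list(x) && all(c("t", "z", "w") %in% names(x)))
    return(drive_params(x$t, x$z, x$w))
  stop("cannot interpret `params` as drive parameters")
}
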