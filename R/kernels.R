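#' Smoothing kernel specification
#'
#' Kernels are symmetric, nonnegative densities used both for the mean
#' smoother and for the local Frechet regression weights.  Scaled
#' evaluation follows `K_h(u) = K(u / h) / h`; with two covariates a
#' product kernel with per-dimension bandwidths is used.
#'
#' @param family `"gaussian"` (default; unbounded support, so local designs
#'   stay nonsingular even in sparse age ranges) or `"epanechnikov"`.
#' @return an object of class `kernel_spec`.
#' @examples
#' k <- kernel_spec("gaussian")
#' kernel_eval(k, 0)                # dnorm(0)
#' kernel_eval(k, 1, bandwidth = 2) # dnorm(0.5)/2
#' @export
kernel_spec <- function(family = c("gaussian", "epanechnikov")) {
  family <- match.arg(family)
  structure(list(family = family), class = "kernel_spec")
}

as_kernel_spec <- function(kernel) {
  if (inherits(kernel, "kernel_spec")) return(kernel)
  if (is.character(kernel) && length(kernel) == 1) return(kernel_spec(kernel))
  stop("`kernel` must be a kernel_spec or a kernel family name")
}

#' Evaluate a scaled kernel
#'
#' @param kernel a [kernel_spec()] or family name.
#' @param u numeric argument(s).
#' @param bandwidth positive scale `h`; `K_h(u) = K(u/h)/h`.
#' @return numeric vector of kernel values.
#' @export
kernel_eval <- function(kernel, u, bandwidth = 1) {
  k <- as_kernel_spec(kernel)
  stopifnot(is.numeric(u), bandwidth > 0)
  z <- u / bandwidth
  v <- switch(k$family,
    gaussian = stats::dnorm(z),
    epanechnikov = ifelse(abs(z) < 1, 0.75 * (1 - z^2), 0)
  )
  v / bandwidth
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: %s>\n", x$family))
  invisible(x)
}
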