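# internal helpers shared across modules

#' Rule-of-thumb kernel bandwidth
#'
#' Normal-reference rule `1.06 * sd(x) * n^(-1/5)`, the package default for
#' both the mean smoother and the Frechet regression weights.  `n` can be
#' overridden so that a pooled spread can be combined with a group-specific
#' sample size.
#'
#' @param x numeric covariate values.
#' @param n sample size used in the rate factor (default `length(x)`).
#' @return a positive bandwidth on the scale of `x`.
#' @export
rule_of_thumb_bandwidth <- function(x, n = length(x)) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop("cannot derive a bandwidth: covariate has zero spread")
  1.06 * s * n^(-1 / 5)
}

# full-precision number formatting for text outputs (bitwise reproducible)
fmt_num <- function(x) sprintf("%.15g", x)

# write a square matrix with labels as CSV, full precision
write_matrix_csv <- function(m, path, labels = NULL) {
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("v%03d", seq_len(nrow(m)))
  lines <- c(
    paste(c("", labels), collapse = ","),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(labels[i], fmt_num(m[i, ])), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

read_matrix_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

# stage-level logging; suppress with options(dynscn.quiet = TRUE)
scn_log <- function(...) {
  if (isTRUE(getOption("dynscn.quiet", FALSE))) return(invisible())
  message(sprintf("[dynscn %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
  invisible()
}

# map a kernel argument (string or kernel_spec) to the integer code used in
# the compiled code
kernel_code <- function(kernel) {
  k <- as_kernel_spec(kernel)
  match(k$family, c("gaussian", "epanechnikov")) - 1L
}

length_rule_code <- function(length_rule) {
  lr <- match.arg(length_rule, c("weight", "inverse"))
  match(lr, c("weight", "inverse")) - 1L
}

measure_code <- function(measure) {
  m <- match.arg(measure, c("modularity", "global_efficiency"))
  match(m, c("modularity", "global_efficiency")) - 1L
}

# derive a stream seed below 2^31 from a base seed and a label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}
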