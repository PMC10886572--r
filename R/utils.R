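#' @useDynLib mirsecretome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov chisq.test dhyper fisher.test median p.adjust pchisq
#'   phyper pnorm rbinom rexp rlnorm rnbinom rnorm runif sd t.test var
#'   complete.cases as.dist cor cutree hclust TukeyHSD setNames quantile rchisq
#' @importFrom utils read.delim write.table head
NULL

stop_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a probability-like scalar
#' @noRd
check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop_input(name, " must be a probability in ", if (open) "(0,1)" else "[0,1]")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
  if (!ok) stop_input(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

rna_alphabet <- c("A", "C", "G", "U")
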