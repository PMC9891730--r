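#' @importFrom stats cor cor.test loess median p.adjust predict prop.test
#'   qchisq quantile rnbinom rnorm rpois runif sd setNames var wilcox.test
#'   rbinom aggregate
#' @importFrom utils head read.delim write.table
NULL

# internal assertion helpers ------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                              strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single non-missing number")
  if (integer && x != round(x)) stop_field(field, "must be an integer")
  if (strict_lower && x <= lower)
    stop_field(field, sprintf("must be > %s", lower))
  if (!strict_lower && x < lower)
    stop_field(field, sprintf("must be >= %s", lower))
  if (x > upper) stop_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

assert_proportion <- function(x, field) {
  assert_scalar_num(x, field, lower = 0, upper = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contiguous re-labelling of cluster ids to 0..K-1, largest cluster first
# (ties broken by old label order).  Returns an integer vector.
relabel_clusters <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- setNames(seq_along(tab) - 1L, names(tab))
  unname(map[as.character(labels)])
}
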