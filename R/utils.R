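# shared internal helpers

#' @importFrom stats median mad quantile rnorm runif rlnorm rpois rbinom
#'   wilcox.test fisher.test cor.test phyper p.adjust lm coef setNames
#'   complete.cases pnorm cor
#' @importFrom utils read.table write.table head tail
NULL

# run `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# named substream: deterministic child seed so that adding emission steps
# does not perturb draws of earlier ones; kept below 2^31
substream_seed <- function(seed, name) {
  h <- sum(as.integer(charToRaw(name)) * seq_along(charToRaw(name)) * 131L)
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 1000003L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0
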