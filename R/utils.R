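#' @keywords internal
"_PACKAGE"

#' @importFrom stats median qt rnorm runif rgamma sd t.test wilcox.test p.adjust setNames
#' @importFrom utils read.table write.table head
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Configuration errors (bad specs/parameters) vs data errors (bad records) are
# distinguished by condition class so callers and the CLI can map them to exit codes.
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("pmtr_config_error", "pmtr_error")))
}

data_error <- function(msg) {
  stop(errorCondition(msg, class = c("pmtr_data_error", "pmtr_error")))
}

parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("pmtr_parse_error", "pmtr_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a sequence string into single residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# run code under a local seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  code
}
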