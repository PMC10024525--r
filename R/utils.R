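#' @importFrom stats setNames
#' @importFrom utils write.csv read.csv head
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Condition helpers. Error classes mirror the failure taxonomy used across the
# package: io, type, contract (precondition broken by the caller), alignment
# (grids/legends disagree), validation (bad data values), mapping (crosswalk
# gaps).
abort <- function(msg, class) {
  stop(structure(
    class = c(paste0("esmapr_", class, "_error"), "esmapr_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state after.
# All generators go through this so they are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Fixed offsets expanding one global seed into per-component sub-seeds,
# kept below 2^31 - 1.
sub_seed <- function(seed, component) {
  offs <- c(landscape = 11L, transitions = 23L, zones = 37L, studies = 53L)
  (as.integer(seed) %% 2000000000L) + offs[[component]]
}

rel_close <- function(a, b, tol = 1e-9) {
  abs(a - b) <= tol * pmax(abs(a), abs(b), 1)
}

msg_info <- function(...) message("[esmapr] ", ...)
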