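## Internal helpers: typed conditions and seed scoping.

## Condition classes map to CLI exit codes:
##   ccsspUsageError      -> 2 (bad parameters / flags)
##   ccsspDataError       -> 3 (invalid files / objects)
##   ccsspNumericalError  -> 4 (singularity, degenerate numerics)
stopUsage <- function(...) {
  stop(errorCondition(paste0(...), class = c("ccsspUsageError", "ccsspError")))
}

stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("ccsspDataError", "ccsspError")))
}

stopNumerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("ccsspNumericalError", "ccsspError")))
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## The two condition codes, by the canonical rule: smaller stored label -> condition 1.
conditionLabels <- function(labels) {
  u <- sort(unique(as.integer(labels)))
  if (length(u) != 2L)
    stopData("expected exactly two distinct labels, found ", length(u))
  u
}

## Map arbitrary binary labels to integer conditions 1/2.
asConditions <- function(labels) {
  u <- conditionLabels(labels)
  ifelse(as.integer(labels) == u[1L], 1L, 2L)
}
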