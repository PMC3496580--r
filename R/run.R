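# Runner: local, sequential execution of a compiled pipeline with error
# capture. Composition and execution are deliberately separate; execution is
# a plain sequence of shell calls in a working directory, halting at the
# first failing step because later steps consume earlier outputs.

#' Execute a compiled pipeline
#'
#' Checks that every required input file (`ep$li`) is present in `workdir`,
#' then runs each command in order with `workdir` as the working directory.
#' Standard error from every step is appended to `pipeline.err`, prefixed
#' with the step number and a timestamp. Execution halts at the first
#' command exiting non-zero.
#'
#' @param ep An `executable_pipeline`.
#' @param workdir Directory holding the input files; outputs are produced
#'   here too.
#' @return An object of class `run_result`: `succeeded` (flag),
#'   `completed_steps`, `err_log` (path to `pipeline.err`) and `produced`
#'   (paths of the declared output files that exist). `succeeded` is `TRUE`
#'   iff all commands completed and all declared outputs exist.
#' @export
run_pipeline <- function(ep, workdir) {
  stopifnot(inherits(ep, "executable_pipeline"))
  if (!dir.exists(workdir)) {
    pg_stop("pg_io_error", sprintf("working directory not found: %s", workdir))
  }
  present <- file.exists(file.path(workdir, ep$li))
  if (!all(present)) {
    pg_stop("pg_missing_input",
            sprintf("missing required input file(s): %s",
                    paste(ep$li[!present], collapse = ", ")))
  }
  err_log <- file.path(workdir, "pipeline.err")
  completed <- 0L
  old <- setwd(workdir)
  on.exit(setwd(old), add = TRUE)
  for (k in seq_along(ep$commands)) {
    errs <- suppressWarnings(
      system2("sh", c("-c", shQuote(ep$commands[k])), stdout = FALSE,
              stderr = TRUE)
    )
    status <- attr(errs, "status") %||% 0L
    if (length(errs) || status != 0L) {
      cat(sprintf("[step %d | %s | exit %d] %s\n", k,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), status,
                  ep$commands[k]),
          file = err_log, append = TRUE)
      if (length(errs)) {
        cat(paste0("  ", as.character(errs), collapse = "\n"), "\n",
            sep = "", file = err_log, append = TRUE)
      }
    }
    if (status != 0L) break
    completed <- k
  }
  produced_mask <- file.exists(file.path(workdir, ep$lo))
  structure(list(
    succeeded = completed == length(ep$commands) && all(produced_mask),
    completed_steps = completed,
    err_log = err_log,
    produced = file.path(workdir, ep$lo[produced_mask])
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s: %d step(s) completed, %d output file(s)\n",
              if (x$succeeded) "succeeded" else "FAILED",
              x$completed_steps, length(x$produced)))
  invisible(x)
}
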