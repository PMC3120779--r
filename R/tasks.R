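## Asynchronous task queue. Jobs are submitted as a list of pipeline-stage
## closures; a cooperative single worker runs stages in FIFO order and
## checks the cancellation flag between stages. Completed tasks are light
## objects holding only the result URI.

newUUID <- function() {
  hex <- sprintf("%x", sample.int(16L, 32L, replace = TRUE) - 1L)
  paste(c(paste(hex[1:8], collapse = ""), paste(hex[9:12], collapse = ""),
          paste(hex[13:16], collapse = ""), paste(hex[17:20], collapse = ""),
          paste(hex[21:32], collapse = "")), collapse = "-")
}

#' Submit a job to the task queue
#'
#' @param store an OTStore.
#' @param stages list of functions; each receives the previous stage's
#'   return value (the first receives NULL) and the last must return the
#'   result URI. Cancellation is honored between stages.
#' @return the new task UUID (status Queued).
#' @export
submitJob <- function(store, stages) {
  id <- newUUID()
  store@env$tasks[[id]] <- list(task = otTask(id), stages = stages)
  store@env$taskQueue <- c(store@env$taskQueue, id)
  id
}

#' Fetch a task record
#' @param store an OTStore.
#' @param id task UUID.
#' @return the \linkS4class{OTTask}, or NULL when unknown.
#' @export
getTask <- function(store, id) {
  force(id)
  rec <- store@env$tasks[[id]]
  if (is.null(rec)) NULL else rec$task
}

setTask <- function(store, id, task) {
  rec <- store@env$tasks[[id]]
  rec$task <- task
  store@env$tasks[[id]] <- rec
}

#' Run the next queued task to completion (or cancellation)
#'
#' @param store an OTStore.
#' @return the UUID of the executed task, or NULL when the queue is empty.
#' @export
taskStep <- function(store) {
  e <- store@env
  while (length(e$taskQueue)) {
    id <- e$taskQueue[1]
    e$taskQueue <- e$taskQueue[-1]
    rec <- e$tasks[[id]]
    if (is.null(rec) || rec$task@status != "Queued") next  # cancelled/stale
    t <- rec$task; t@status <- "Running"; setTask(store, id, t)
    value <- NULL
    failed <- FALSE
    for (stage in rec$stages) {
      cur <- getTask(store, id)
      if (cur@status == "Cancelled") return(id)
      value <- tryCatch(stage(value), error = function(err) {
        msg <- conditionMessage(err)
        setTask(store, id, otTask(id, status = "Error", errorMessage = msg,
                                  created = cur@created,
                                  completed = as.numeric(Sys.time())))
        failed <<- TRUE
        NULL
      })
      if (failed) return(id)
    }
    cur <- getTask(store, id)
    if (cur@status == "Cancelled") return(id)
    setTask(store, id, otTask(id, status = "Completed",
                              resultUri = as.character(value),
                              created = cur@created,
                              completed = as.numeric(Sys.time())))
    return(id)
  }
  NULL
}

#' Drain the task queue
#' @param store an OTStore.
#' @return invisibly, the number of tasks executed.
#' @export
taskRunAll <- function(store) {
  n <- 0L
  while (!is.null(taskStep(store))) n <- n + 1L
  invisible(n)
}

#' Cancel a task
#'
#' Queued tasks are cancelled immediately and never run; running tasks are
#' flagged and stop at the next pipeline-stage boundary; completed tasks
#' are left untouched.
#'
#' @param store an OTStore.
#' @param id task UUID.
#' @return the updated \linkS4class{OTTask}.
#' @export
cancelTask <- function(store, id) {
  t <- getTask(store, id)
  if (is.null(t)) stop(otCondition(404, paste("unknown task:", id)))
  if (t@status %in% c("Queued", "Running")) {
    setTask(store, id, otTask(id, status = "Cancelled", created = t@created,
                              completed = as.numeric(Sys.time())))
  }
  getTask(store, id)
}
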