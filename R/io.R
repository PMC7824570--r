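# Delimited-text readers/writers for datasets, posterior summaries and
# draws, JSON run manifests.  Comma-separated, period decimal, mandatory
# header, UTF-8; numbers carry 17 significant digits for lossless
# round-trips.

fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE),
         formatC(x, digits = 17, format = "g"))
}

write_table_17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a joint dataset to delimited files
#'
#' Longitudinal rows (\code{id, time, y, x}) and survival rows
#' (\code{id, T, delta, x}) are written in deterministic order (by id,
#' then time) with 17 significant digits, so a write/read cycle is exact
#' and repeated writes are byte-identical.
#'
#' @param data a \code{joint_data} object.
#' @param long_path,surv_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_joint_dataset <- function(data, long_path, surv_path) {
  stopifnot(inherits(data, "joint_data"))
  long <- data$longitudinal
  long <- long[order(long$id, long$time), c("id", "time", "y", "x")]
  surv <- data$survival
  surv <- surv[order(surv$id), c("id", "T", "delta", "x")]
  write_table_17(long, long_path)
  write_table_17(surv, surv_path)
  invisible(c(long_path, surv_path))
}

#' Read a joint dataset from delimited files
#'
#' Assembles subjects by id and validates the record invariants:
#' measurement times sorted and not beyond the observed time, event
#' indicator in \{0, 1\}, group indicator constant within subject and
#' consistent across the two files.  Violations raise errors naming the
#' offending id or row.
#'
#' @param long_path CSV with columns \code{id, time, y, x}.
#' @param surv_path CSV with columns \code{id, T, delta, x}.
#' @return A \code{joint_data} object (without simulation provenance).
#' @export
read_joint_dataset <- function(long_path, surv_path) {
  long <- utils::read.csv(long_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(surv_path, stringsAsFactors = FALSE)
  need_l <- c("id", "time", "y", "x")
  need_s <- c("id", "T", "delta", "x")
  if (!all(need_l %in% names(long))) {
    stop("longitudinal file must have columns ", paste(need_l, collapse = ","))
  }
  if (!all(need_s %in% names(surv))) {
    stop("survival file must have columns ", paste(need_s, collapse = ","))
  }
  missing_ids <- setdiff(long$id, surv$id)
  if (length(missing_ids)) {
    stop("id(s) present in longitudinal but not in survival file: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  if (!all(surv$delta %in% c(0, 1))) {
    bad <- which(!surv$delta %in% c(0, 1))[1]
    stop("invalid delta at survival row ", bad)
  }
  if (any(surv$T <= 0)) stop("observed times must be > 0")
  long <- long[order(long$id, long$time), ]
  surv <- surv[order(surv$id), ]
  Tmap <- stats::setNames(surv$T, surv$id)
  xmap <- stats::setNames(surv$x, surv$id)
  over <- which(long$time > Tmap[as.character(long$id)] + 1e-12)
  if (length(over)) {
    stop("measurement time exceeds observed time at longitudinal row ",
         over[1], " (id ", long$id[over[1]], ")")
  }
  xbad <- which(long$x != xmap[as.character(long$id)])
  if (length(xbad)) {
    stop("group indicator inconsistent across files at longitudinal row ",
         xbad[1], " (id ", long$id[xbad[1]], ")")
  }
  dup <- stats::ave(long$time, long$id,
                    FUN = function(t) c(FALSE, diff(t) <= 0))
  if (any(dup == 1)) {
    stop("measurement times not strictly increasing for id ",
         long$id[which(dup == 1)[1]])
  }
  rownames(long) <- rownames(surv) <- NULL
  structure(list(longitudinal = long, survival = surv, b = NULL,
                 event_rate = mean(surv$delta), config = NULL),
            class = "joint_data")
}

#' Write the posterior-summary table of a fit
#'
#' @param fit a \code{jm_fit}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_posterior_summary <- function(fit, path) {
  write_table_17(posterior_summary(fit), path)
  invisible(path)
}

#' Write posterior draws in long columnar layout
#'
#' One row per (parameter, chain, iteration) with the drawn value; the
#' layout is self-describing and loads with any CSV reader.
#'
#' @param fit a \code{jm_fit}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_draws <- function(fit, path) {
  rows <- lapply(names(fit$draws), function(p) {
    d <- as.matrix(fit$draws[[p]])
    data.frame(parameter = p,
               chain = rep(seq_len(ncol(d)), each = nrow(d)),
               iteration = rep(seq_len(nrow(d)), ncol(d)),
               value = as.vector(d))
  })
  write_table_17(do.call(rbind, rows), path)
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to regenerate a run: command, resolved
#' configuration, master seed, package version, input/output file digests
#' and timestamps.
#'
#' @param command name of the command executed.
#' @param config list of resolved configuration values (must be
#'   JSON-serialisable).
#' @param seed master seed of the run.
#' @param inputs,outputs character vectors of file paths to digest.
#' @return A list of class \code{"run_manifest"}.
#' @export
run_manifest <- function(command, config, seed, inputs = character(0),
                         outputs = character(0)) {
  digest <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(tools::md5sum(paths))
  }
  structure(list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("twostagejm")),
    input_digests = digest(inputs),
    output_digests = digest(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write a manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
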