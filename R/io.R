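#' Read and write titration curves as CSV
#'
#' Plain CSV with columns `volume_mL`, `reading`, `reading_kind`,
#' `replicate`; a versioned header comment carries the acid excess so a
#' written curve can be refined after reloading (the protocol must be
#' supplied on read).
#'
#' @param curves a `titration_curve` or list of them.
#' @param path file path.
#' @export
write_titration_csv <- function(curves, path) {
  if (inherits(curves, "titration_curve")) curves <- list(curves)
  acid <- attr(curves[[1]], "acid_excess")
  tab <- do.call(rbind, lapply(curves, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pdmaspec titration v1 acid_excess=%.12g",
                     if (is.null(acid)) NA_real_ else acid), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration_csv
#' @param protocol the [titration_protocol()] to reattach.
#' @export
read_titration_csv <- function(path, protocol = NULL) {
  lines <- readLines(path)
  hdr <- grep("^# pdmaspec titration", lines, value = TRUE)
  acid <- if (length(hdr))
    as.numeric(sub(".*acid_excess=", "", hdr[1])) else NA_real_
  tab <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                      collapse = "\n"),
                         stringsAsFactors = FALSE)
  lapply(split(tab, tab$replicate), function(d) {
    rownames(d) <- NULL
    attr(d, "protocol") <- protocol
    attr(d, "acid_excess") <- acid
    class(d) <- c("titration_curve", "data.frame")
    d
  })
}

#' Serialize a refinement result to JSON
#'
#' @param result a `refinement_result`.
#' @param path file path.
#' @export
write_refinement_json <- function(result, path) {
  out <- list(format = "pdmaspec-refinement-v1",
              estimates = as.list(result$estimates),
              sigma = as.list(result$sigma),
              I_ref = result$I_ref,
              converged = result$converged,
              deviance = result$deviance,
              per_curve = result$per_curve)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a run manifest next to an output file
#'
#' Records command, configuration, database version, seed and timestamp so
#' any output table can be regenerated.  Written atomically (temp file then
#' rename).
#'
#' @param command short description of the operation.
#' @param output_paths character vector of the files the run produced.
#' @param db the `equilibrium_database` used.
#' @param seed integer seed in force (or NA).
#' @param config optional configuration object (stored as JSON).
#' @param path manifest path; default first output path + `.manifest.json`.
#' @export
write_run_manifest <- function(command, output_paths, db, seed = NA,
                               config = NULL, path = NULL) {
  if (is.null(path)) path <- paste0(output_paths[1], ".manifest.json")
  man <- list(command = command,
              outputs = output_paths,
              database_version = db$version,
              database_hash = db_hash(db),
              seed = seed,
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"),
              config = config)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

# deterministic content hash of the database's numeric payload
db_hash <- function(db) {
  payload <- paste(c(db$species$species, format(db$species$log_beta0,
                                                digits = 12),
                     db$redox_couples$species,
                     format(db$redox_couples$log_beta0, digits = 12)),
                   collapse = "|")
  ## small polynomial rolling hash; avoids external digest dependencies
  h <- 17
  for (ch in utf8ToInt(payload)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
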