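# TSV/JSON interfaces. TSV with a header row is the canonical matrix format;
# every numeric artifact can carry a JSON sidecar describing its provenance.

# write.table prints doubles at 15 significant digits; %.17g guarantees
# bit-exact round-trips for all artifacts.
write_tsv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a labelled square matrix as TSV
#'
#' The first column (`region`) holds row labels; remaining columns are the
#' region-labelled matrix entries, written at full precision.
#'
#' @param m matrix or `corr_matrix`.
#' @param path file path.
#' @param sidecar optional list written as `<path>.json` (role, subject and
#'   any parameters are added automatically for `corr_matrix` input).
#' @return `read_matrix_tsv` returns a matrix (with a `corr_matrix` rebuilt
#'   when the sidecar declares a role); `write_matrix_tsv` returns `path`
#'   invisibly.
#' @export
write_matrix_tsv <- function(m, path, sidecar = NULL) {
  obj <- m
  m <- unclass_corr(m)
  stopifnot(is.matrix(m))
  rn <- rownames(m) %||% sprintf("R%03d", seq_len(nrow(m)))
  df <- data.frame(region = rn, m, check.names = FALSE)
  colnames(df) <- c("region", colnames(m) %||% rn)
  write_tsv_full(df, path)
  if (inherits(obj, "corr_matrix")) {
    sidecar <- c(list(role = obj$role, subject = obj$subject), sidecar)
  }
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "region") stop("matrix TSV must start with a 'region' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$role) && side$role %in%
        c("SC", "rNC", "tNC", "NC", "deltaNC", "differential")) {
      return(corr_matrix(m, role = side$role, subject = side$subject %||% "group"))
    }
  }
  m
}

#' Write / read a beta series as TSV
#'
#' One row per block: metadata columns (`block_id`, `task`, `block_index`,
#' `state`) followed by one column per region. Numeric values round-trip at
#' full double precision.
#'
#' @param beta a [beta_series()].
#' @param path file path.
#' @param subject subject id to record on read (read from the sidecar when
#'   present).
#' @return `read_beta_series` returns a [beta_series()];
#'   `write_beta_series` returns `path` invisibly.
#' @export
write_beta_series <- function(beta, path) {
  stopifnot(inherits(beta, "beta_series"))
  df <- cbind(beta$meta[, c("block_id", "task", "block_index", "state")],
              as.data.frame(t(beta$coef), check.names = FALSE))
  write_tsv_full(df, path)
  jsonlite::write_json(list(subject = beta$subject,
                            n_regions = nrow(beta$coef),
                            n_blocks = ncol(beta$coef)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beta_series
#' @export
read_beta_series <- function(path, subject = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  metacols <- c("block_id", "task", "block_index", "state")
  missing <- setdiff(metacols, names(df))
  if (length(missing)) {
    stop("beta series TSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  side_path <- paste0(path, ".json")
  if (is.null(subject) && file.exists(side_path)) {
    subject <- jsonlite::read_json(side_path)$subject
  }
  coef <- t(as.matrix(df[, setdiff(names(df), metacols), drop = FALSE]))
  beta_series(coef, df[, metacols], subject = subject %||% "sub-01")
}

#' Read / write a BIDS-style events table
#'
#' Tab-separated with at least `onset`, `duration`, `trial_type` columns;
#' onsets must be strictly increasing and blocks non-overlapping.
#'
#' @param path file path.
#' @param events events data frame.
#' @return `read_events` returns a validated events data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_events(df)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  utils::write.table(events[, intersect(c("onset", "duration", "trial_type"),
                                        names(events))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a region-to-network partition as two-column TSV
#'
#' Columns `region_id` and `network_label`; duplicate regions are an error.
#'
#' @param path file path.
#' @param partition a [network_partition()].
#' @return `read_partition` returns a [network_partition()].
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("region_id", "network_label"), names(df))
  if (length(missing)) {
    stop("partition TSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  network_partition(df$region_id, df$network_label)
}

#' @rdname read_partition
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "network_partition"))
  utils::write.table(data.frame(region_id = partition$region,
                                network_label = partition$label),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a parcellated time series as TSV (frames x regions)
#'
#' @param ts a [parcel_timeseries()].
#' @param path file path.
#' @return `read_timeseries_tsv` returns a [parcel_timeseries()].
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  write_tsv_full(as.data.frame(ts$data, check.names = FALSE), path)
  jsonlite::write_json(list(tr = ts$tr), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @param tr repetition time, used if no sidecar is present.
#' @export
read_timeseries_tsv <- function(path, tr = 1) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    tr <- jsonlite::read_json(side_path)$tr %||% tr
  }
  parcel_timeseries(as.matrix(df), tr = tr)
}
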