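#' Read a trajectory CSV
#'
#' The interchange format is one row per stored frame with header columns
#' `airineme_id`, `frame`, `t_min`, `x_um`, `y_um` (coordinates in um,
#' time in min; an optional `heading_rad` column is preserved). Rows are
#' grouped by `airineme_id` and sorted by `frame`; malformed input fails
#' with the offending rows named.
#'
#' @param path CSV file path.
#' @return A trajectory tibble.
#' @export
read_trajectories <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("airineme_id", "frame", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- c("frame", "t_min", "x_um", "y_um")
  bad <- which(!complete.cases(df[num]) |
                 !apply(is.finite(as.matrix(df[num])), 1, all))
  if (length(bad) > 0) {
    stop("non-finite values at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[c("airineme_id", "frame")])
  if (any(dup)) {
    d <- df[which(dup)[1], ]
    stop("duplicated (airineme_id, frame) pair: (", d$airineme_id, ", ",
         d$frame, ")", call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$airineme_id, .data$frame)
  mono <- df |>
    dplyr::group_by(.data$airineme_id) |>
    dplyr::summarise(ok = all(diff(.data$t_min) > 0), .groups = "drop")
  if (any(!mono$ok)) {
    stop("non-monotone t_min within airineme_id: ",
         paste(mono$airineme_id[!mono$ok], collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a trajectory table to CSV
#'
#' @param trajectories Trajectory tibble (see [read_trajectories()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trajectories <- function(trajectories, path) {
  assert_trajectories(trajectories)
  readr::write_csv(trajectories, path)
  invisible(path)
}

result_payload <- function(result) {
  if (inherits(result, "prw_ensemble")) {
    list(type = "ensemble",
         params = unclass(result$params),
         n = result$n, n_contacts = result$n_contacts,
         p_contact = result$p_contact,
         ci90 = as.numeric(result$ci90),
         contact_angles_rad = as.numeric(result$contact_angles),
         seed = result$seed)
  } else if (inherits(result, "prw_dtheta_fit")) {
    c(list(type = "dtheta_fit"), as.list(glance(result)))
  } else if (inherits(result, "prw_msd_fit")) {
    c(list(type = "msd_fit"), as.list(glance(result)))
  } else if (inherits(result, "prw_ccdf_fit")) {
    c(list(type = "ccdf_fit"), as.list(glance(result)))
  } else if (is.data.frame(result)) {
    list(type = "table", data = result)
  } else {
    list(type = "list", data = result)
  }
}

#' Write an analysis result as JSON
#'
#' Serialises any package result (ensembles, fits, sweep/trade-off tables,
#' plain lists) together with reproducibility metadata: the package
#' version, an ISO-8601 timestamp, and any `config` supplied. Numeric
#' fields keep full precision, so re-running with the same configuration
#' and seed reproduces the numeric payload bit-identically.
#'
#' @param result The object to serialise.
#' @param path Output JSON path.
#' @param config Optional named list recording the run configuration.
#' @return Invisibly, `path`.
#' @export
write_results <- function(result, path, config = NULL) {
  payload <- list(
    package = "prwsearch",
    version = as.character(utils::packageVersion("prwsearch")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    result = result_payload(result)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a JSON result file
#'
#' @param path JSON path written by [write_results()].
#' @return The parsed list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
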