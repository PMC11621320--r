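#' Read and write trajectory tables
#'
#' Trajectories are stored as plain-text CSV with one header row and the
#' columns `trial_id, age, t, fish_id, color, x, y, heading_deg`.
#' Coordinates are written with 6 decimals, so a write/read round trip is
#' lossless at that precision. Malformed files are rejected with
#' line-numbered errors.
#'
#' @param traj trajectory `data.table` (internal column `t_step` is
#'   written as `t`)
#' @param path file path
#' @return `write_trajectories`: the path, invisibly;
#'   `read_trajectories`: a trajectory `data.table`
#' @export
write_trajectories <- function(traj, path) {
  traj <- data.table::as.data.table(traj)
  out <- traj[, .(trial_id, age, t = t_step, fish_id, color,
                  x = round(x, 6), y = round(y, 6),
                  heading_deg = round(heading_deg, 6))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path)
  need <- c("trial_id", "age", "t", "fish_id", "color", "x", "y",
            "heading_deg")
  dt <- tryCatch(
    suppressWarnings(data.table::fread(path)),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if ("color" %in% names(dt)) dt[, color := as.character(color)]
  if (!all(need %in% names(dt)))
    stop("malformed trajectory file ", path, " (line 1): missing columns ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  num_cols <- setdiff(need, "color")
  for (cc in num_cols) {
    v <- dt[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("malformed trajectory file ", path, " (line ", bad + 1,
           "): non-numeric value in column ", cc)
    }
  }
  if (anyNA(dt[, ..num_cols])) {
    bad <- which(rowSums(is.na(dt[, ..num_cols])) > 0)[1]
    stop("malformed trajectory file ", path, " (line ", bad + 1,
         "): missing value")
  }
  data.table::setnames(dt, "t", "t_step")
  dt[]
}
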