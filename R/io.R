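measurement_cols <- c("spheroid_id", "day", "condition",
                      "R_o_um", "R_n_um", "R_i_um", "R_p_um")

#' Read a radial-measurement table
#'
#' Comma-separated, one row per spheroid per end-point measurement, header
#' `spheroid_id, day, condition, R_o_um, R_n_um, R_i_um, R_p_um`; radii in
#' micrometres, empty cells are missing values. Structure radii recorded as
#' 0 mean "region not formed", not missing.
#'
#' @param path file path.
#' @return A `data.frame` with the columns above, `day` and radii numeric.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(measurement_cols, names(tab))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("day", "R_o_um", "R_n_um", "R_i_um", "R_p_um")) {
    suppressWarnings(num <- as.numeric(tab[[col]]))
    bad <- which(!is.na(tab[[col]]) & tab[[col]] != "" & is.na(num))
    if (length(bad) > 0)
      stop("malformed numeric values in column ", col, " at data row(s) ",
           paste(bad, collapse = ", "))
    tab[[col]] <- num
  }
  tab[measurement_cols]
}

#' Write a radial-measurement table
#'
#' Inverse of [read_measurements()]; missing values are written as empty
#' cells. Numeric formatting is pinned (15 significant digits) so identical
#' tables serialize byte-identically.
#'
#' @param tab measurement table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(tab, path) {
  stopifnot(all(measurement_cols %in% names(tab)))
  out <- tab[measurement_cols]
  for (col in c("day", "R_o_um", "R_n_um", "R_i_um", "R_p_um"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 15, format = "g"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a radial-measurement table
#'
#' Checks the nesting invariants per row: radii non-negative, `R_n <= R_o`,
#' `R_i <= R_o`, `R_p` (when present) in `[0, R_o]`. Rows with `R_i < R_n`
#' are reported separately: plausible under measurement noise, they are kept
#' but profile evaluation clips them.
#'
#' @param tab measurement table.
#' @return A list: `valid` (logical per row), `issues` (data frame of row
#'   index and message), `n_Ri_below_Rn`.
#' @export
validate_measurements <- function(tab) {
  stopifnot(all(measurement_cols %in% names(tab)))
  n <- nrow(tab)
  valid <- rep(TRUE, n)
  issues <- list()
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      valid[rows] <<- FALSE
      issues[[length(issues) + 1]] <<- data.frame(row = rows, issue = msg)
    }
  }
  note(which(tab$R_o_um <= 0 | is.na(tab$R_o_um)), "R_o missing or <= 0")
  note(which(tab$R_n_um < 0 | tab$R_i_um < 0), "negative structure radius")
  note(which(tab$R_n_um > tab$R_o_um), "R_n exceeds R_o")
  note(which(tab$R_i_um > tab$R_o_um), "R_i exceeds R_o")
  note(which(!is.na(tab$R_p_um) &
               (tab$R_p_um < 0 | tab$R_p_um > tab$R_o_um)),
       "R_p outside [0, R_o]")
  soft <- which(tab$R_i_um > 0 & tab$R_i_um < tab$R_n_um)
  list(valid = valid,
       issues = if (length(issues) > 0) do.call(rbind, issues)
                else data.frame(row = integer(), issue = character()),
       n_Ri_below_Rn = length(soft))
}

#' Convert a projected area to an equivalent radius
#'
#' `r = sqrt(A / pi)`, the radius of the circle with the measured
#' equatorial-plane area.
#'
#' @param A area(s) \[um^2\], non-negative.
#' @return Radius \[um\].
#' @export
area_to_radius <- function(A) {
  if (any(!is.finite(A)) || any(A < 0)) stop("area must be non-negative")
  sqrt(A / pi)
}

#' Write a model trajectory as delimited text
#'
#' @param traj a `spheroid_trajectory` (or `switching_trajectory`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "spheroid_trajectory"))
  out <- as.data.frame(traj)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    formatC(x, digits = 15, format = "g"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
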