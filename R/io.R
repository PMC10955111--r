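# Plain-text artifact formats: TSV with typed "# key: value" header lines
# for series/profiles/paths, JSON for configs and reports. Numeric values
# are written with 17 significant digits so read(write(x)) round-trips to
# full double precision.

.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.write_tsv_with_header <- function(df, header, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (nm in names(header)) {
    writeLines(paste0("# ", nm, ": ", header[[nm]]), con)
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) .fmt_num(col) else as.character(col)
  }), sep = "\t"))
  writeLines(body, con)
  invisible(file)
}

.read_tsv_with_header <- function(file) {
  lines <- readLines(file)
  hdr_idx <- grep("^# ", lines)
  header <- list()
  for (ln in lines[hdr_idx]) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    header[[key]] <- sub("^[^:]*: ?", "", kv)
  }
  body <- lines[-hdr_idx]
  cols <- strsplit(body[1], "\t")[[1]]
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = cols, na.strings = "NA",
                           stringsAsFactors = FALSE)
  list(header = header, data = dat)
}

.require_header_temperature <- function(header) {
  t <- suppressWarnings(as.numeric(header$temperature_K))
  if (is.null(header$temperature_K) || is.na(t) || t <= 0) {
    stop("invalid or missing header temperature (temperature_K = ",
         header$temperature_K %||% "<absent>", ")", call. = FALSE)
  }
  t
}

#' Write a trajectory to TSV
#'
#' @param trajectory An `lk_trajectory`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, file) {
  stopifnot(inherits(trajectory, "lk_trajectory"))
  md <- trajectory$metadata
  .write_tsv_with_header(
    trajectory$columns,
    list(type = "loopkin_trajectory",
         dt_ps = .fmt_num(trajectory$dt),
         temperature_K = .fmt_num(md$temperature),
         mass = .fmt_num(md$mass),
         seed = md$seed,
         bias = jsonlite::toJSON(md$bias, auto_unbox = TRUE,
                                 digits = NA),
         bath_labels = paste(md$bath_labels, collapse = ",")),
    file)
}

#' Read a trajectory written by [write_trajectory_tsv()]
#'
#' @param file Input path.
#' @return An `lk_trajectory` (full-precision round trip).
#' @export
read_trajectory_tsv <- function(file) {
  x <- .read_tsv_with_header(file)
  if (!identical(x$header$type, "loopkin_trajectory")) {
    stop("not a loopkin trajectory file: ", file, call. = FALSE)
  }
  temperature <- .require_header_temperature(x$header)
  dt <- as.numeric(x$header$dt_ps)
  if (is.na(dt) || dt <= 0) stop("invalid header dt_ps", call. = FALSE)
  labels <- strsplit(x$header$bath_labels %||% "", ",")[[1]]
  structure(list(
    dt = dt,
    time = (seq_len(nrow(x$data)) - 1) * dt,
    columns = x$data,
    length = nrow(x$data),
    metadata = list(temperature = temperature,
                    mass = as.numeric(x$header$mass),
                    seed = suppressWarnings(as.numeric(x$header$seed)),
                    bias = jsonlite::fromJSON(x$header$bias),
                    bath_labels = labels)
  ), class = "lk_trajectory")
}

#' Write a free-energy profile to TSV
#'
#' @param profile An `lk_fep`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_profile_tsv <- function(profile, file) {
  stopifnot(inherits(profile, "lk_fep"))
  df <- data.frame(s = profile$grid, G = profile$G,
                   stderr = profile$stderr)
  .write_tsv_with_header(
    df,
    list(type = "loopkin_profile",
         temperature_K = .fmt_num(profile$temperature),
         bin_width = .fmt_num(profile$bin_width),
         C_s = .fmt_num(profile$C_s)),
    file)
}

#' Read a free-energy profile TSV
#'
#' A missing `stderr` column is read as absent (flagged
#' `stderr_present = FALSE`), never silently as zero.
#'
#' @param file Input path.
#' @return An `lk_fep`.
#' @export
read_profile_tsv <- function(file) {
  x <- .read_tsv_with_header(file)
  if (!identical(x$header$type, "loopkin_profile")) {
    stop("not a loopkin profile file: ", file, call. = FALSE)
  }
  temperature <- .require_header_temperature(x$header)
  stderr_present <- "stderr" %in% names(x$data) &&
    !all(is.na(x$data$stderr))
  structure(list(
    grid = x$data$s, G = x$data$G,
    stderr = if ("stderr" %in% names(x$data)) x$data$stderr else
      rep(NA_real_, nrow(x$data)),
    stderr_present = stderr_present,
    C_s = as.numeric(x$header$C_s),
    temperature = temperature,
    bin_width = as.numeric(x$header$bin_width),
    visited = !is.na(x$data$G)
  ), class = "lk_fep")
}

#' Write a string path to TSV
#'
#' @param path An `lk_path`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_path_tsv <- function(path, file) {
  stopifnot(inherits(path, "lk_path"))
  df <- as.data.frame(path$nodes)
  names(df) <- .cv_names(path$cvs)
  df <- cbind(data.frame(arc_length = path$arc_length), df)
  .write_tsv_with_header(
    df,
    list(type = "loopkin_path",
         s_star = .fmt_num(path$s_star),
         cv_kinds = paste(vapply(path$cvs, function(cv) cv$kind,
                                 character(1)), collapse = ","),
         cv_weights = paste(.fmt_num(path$weights), collapse = ",")),
    file)
}

#' Read a string path TSV
#'
#' @param file Input path.
#' @return An `lk_path`.
#' @export
read_path_tsv <- function(file) {
  x <- .read_tsv_with_header(file)
  if (!identical(x$header$type, "loopkin_path")) {
    stop("not a loopkin path file: ", file, call. = FALSE)
  }
  kinds <- strsplit(x$header$cv_kinds, ",")[[1]]
  weights <- as.numeric(strsplit(x$header$cv_weights, ",")[[1]])
  nm <- setdiff(names(x$data), "arc_length")
  cvs <- lapply(seq_along(nm), function(j) {
    collective_variable(nm[j], kinds[j], weight = weights[j])
  })
  string_path(as.matrix(x$data[nm]), cvs,
              arc_length = x$data$arc_length,
              s_star = as.numeric(x$header$s_star))
}

#' Serialize a kinetics report to JSON
#'
#' Internal consistency is revalidated at serialization: the equilibrium
#' constant must equal the rate ratio and the transmission coefficient the
#' frequency ratio.
#'
#' @param report A `lk_report` from [run_pipeline()].
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_report_json <- function(report, file) {
  .validate_report(report)
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(file)
}

#' Read a kinetics report JSON
#'
#' @param file Input path.
#' @return The report list (revalidated).
#' @export
read_report_json <- function(file) {
  rep <- jsonlite::fromJSON(file)
  .validate_report(rep)
  class(rep) <- "lk_report"
  rep
}

.validate_report <- function(report) {
  rel <- abs(report$K_eq - report$k_opening / report$k_closing) /
    report$K_eq
  if (!is.finite(rel) || rel > 1e-10) {
    stop("inconsistent report: K_eq != k_opening / k_closing",
         call. = FALSE)
  }
  rel_k <- abs(report$kappa_GH - report$omega_r / report$omega_eq)
  if (!is.finite(rel_k) || rel_k > 1e-9) {
    stop("inconsistent report: kappa_GH != omega_r / omega_eq",
         call. = FALSE)
  }
  invisible(TRUE)
}
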