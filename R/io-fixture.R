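#' Read and write trials in the plain-text fixture format
#'
#' A simple UTF-8 CSV dialect for exchanging single trials as text, used for
#' golden tests and for human-inspectable exports. Layout: line 1 is the
#' magic `#gaitdx-fixture v1`; lines 2--4 are `patient_id,<id>`,
#' `form,<1-4>` and `frame_rate,<Hz>`; line 5 is the column header
#' `frame,C7_x,C7_y,C7_z,...` with the 19 markers in canonical order; each
#' following line is one frame, coordinates printed with 6 decimal digits.
#' The round trip `read_fixture(write_fixture(t))` reproduces every field
#' exactly at that precision.
#'
#' @param path file path.
#' @param trial a [gait_trial()].
#' @return `read_fixture` returns a `gait_trial`; `write_fixture` returns
#'   `path` invisibly.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  perr <- function(i, msg) stop("fixture parse error at line ", i, ": ", msg)
  if (length(lines) < 5L) perr(length(lines), "file truncated")
  if (trimws(lines[1]) != "#gaitdx-fixture v1")
    perr(1, "bad magic, expected '#gaitdx-fixture v1'")
  kv <- function(i, key) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L || parts[1] != key)
      perr(i, paste0("expected '", key, ",<value>'"))
    parts[2]
  }
  patient_id <- kv(2, "patient_id")
  form_raw <- kv(3, "form")
  form <- if (form_raw %in% c("NA", "")) NA_integer_ else {
    f <- suppressWarnings(as.integer(form_raw))
    if (is.na(f) || !f %in% 1:4) perr(3, "form must be 1-4 or NA")
    f
  }
  frame_rate <- suppressWarnings(as.numeric(kv(4, "frame_rate")))
  if (is.na(frame_rate) || frame_rate <= 0) perr(4, "bad frame_rate")

  expect_header <- paste(c("frame", paste0(rep(.GAIT_MARKERS, each = 3),
                                           "_", c("x", "y", "z"))),
                         collapse = ",")
  if (lines[5] != expect_header) {
    got <- strsplit(lines[5], ",", fixed = TRUE)[[1]]
    nmk <- (length(got) - 1L) / 3
    if (nmk != 19L)
      perr(5, paste0("header lists ", nmk, " markers, expected 19"))
    bad <- setdiff(sub("_[xyz]$", "", got[-1]), .GAIT_MARKERS)
    if (length(bad))
      perr(5, paste0("unknown marker id(s): ",
                     paste(unique(bad), collapse = ", ")))
    perr(5, "marker columns out of canonical order")
  }
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop("fixture invariant violated: a trial requires >= 2 frames, got ",
         length(body))
  nf <- length(body)
  vals <- matrix(NA_real_, nf, 58L)
  for (i in seq_len(nf)) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 58L)
      perr(i + 5L, paste0("expected 58 columns, got ", length(parts)))
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) perr(i + 5L, "non-numeric value")
    vals[i, ] <- v
  }
  pos <- array(NA_real_, c(nf, 19L, 3L),
               dimnames = list(NULL, .GAIT_MARKERS, c("x", "y", "z")))
  for (m in seq_len(19L)) pos[, m, ] <- vals[, 1L + (m - 1L) * 3L + 1:3]
  gait_trial(pos, frame_rate, patient_id = patient_id, form = form,
             trial_id = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_fixture
#' @export
write_fixture <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  nf <- n_frames(trial)
  header <- paste(c("frame", paste0(rep(.GAIT_MARKERS, each = 3),
                                    "_", c("x", "y", "z"))), collapse = ",")
  flat <- matrix(aperm(trial$positions, c(1, 3, 2)), nrow = nf)  # x,y,z per marker
  rows <- vapply(seq_len(nf), function(i) {
    paste(c(i - 1L, sprintf("%.6f", flat[i, ])), collapse = ",")
  }, character(1))
  writeLines(c("#gaitdx-fixture v1",
               paste0("patient_id,", trial$patient_id),
               paste0("form,", ifelse(is.na(trial$form), "NA", trial$form)),
               paste0("frame_rate,", format(trial$frame_rate, digits = 15)),
               header, rows),
             path, useBytes = TRUE)
  invisible(path)
}
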