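#' Read a motion-capture trial from a C3D file
#'
#' A minimal reader for the standard C3D binary motion-capture format
#' (Intel processor type, integer or floating-point point data). The file
#' must define a POINT group whose LABELS cover the 19 markers of
#' [gait_markers()]; extra point labels (technical markers, subject-prefixed
#' labels such as `"Subj:C7"`) are permitted and ignored. Class label and
#' patient identity are not part of C3D and are supplied as sidecar
#' arguments.
#'
#' @param path path to a C3D file.
#' @param patient_id,form,trial_id sidecar metadata forwarded to
#'   [gait_trial()].
#' @return A [gait_trial()] with markers in canonical order and the frame
#'   rate taken from the file.
#' @export
read_c3d <- function(path, patient_id = NA_character_, form = NA_integer_,
                     trial_id = NULL) {
  if (!file.exists(path)) stop("cannot read C3D file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 512L) stop("cannot read C3D file: truncated header")
  u8  <- function(i) as.integer(raw[i])
  i16 <- function(i) readBin(raw[i + 0:1], "integer", size = 2,
                             endian = "little")
  f32 <- function(i) readBin(raw[i + 0:3], "double", size = 4,
                             endian = "little")
  if (u8(2) != 80L) stop("cannot read C3D file: bad magic byte")
  param_block <- u8(1)
  n_points    <- i16(3)
  first_frame <- i16(7)
  last_frame  <- i16(9)
  hdr_scale   <- f32(13)
  data_block  <- i16(17)
  frame_rate  <- f32(21)

  # --- parameter section ---------------------------------------------------
  p0 <- (param_block - 1L) * 512L
  proc <- u8(p0 + 4L)
  if (proc != 84L)
    stop("unsupported C3D processor type ", proc, " (only Intel/84)")
  groups <- list()   # id -> name
  params <- list()   # "group/param" -> value
  pos <- p0 + 5L
  repeat {
    if (pos > length(raw)) break
    nchar_name <- u8(pos)
    if (nchar_name > 127L) nchar_name <- nchar_name - 256L  # signed
    id <- u8(pos + 1L)
    if (id > 127L) id <- id - 256L
    if (nchar_name == 0L || id == 0L) break
    nm <- rawToChar(raw[(pos + 2L):(pos + 1L + abs(nchar_name))])
    cur <- pos + 2L + abs(nchar_name)
    offset <- i16(cur)
    nxt <- cur + 2L + offset   # offset counts from the byte after the pointer
    if (id < 0L) {                       # group record
      groups[[as.character(-id)]] <- nm
    } else {                             # parameter record
      etype <- u8(cur + 2L); if (etype > 127L) etype <- etype - 256L
      ndims <- u8(cur + 3L)
      dims <- if (ndims > 0L) vapply(seq_len(ndims),
                                     function(k) u8(cur + 3L + k), 0L) else integer(0)
      dstart <- cur + 4L + ndims
      nel <- if (length(dims)) prod(dims) else 1L
      val <- switch(as.character(etype),
        "-1" = rawToChar(raw[dstart:(dstart + nel - 1L)]),
        "1"  = vapply(seq_len(nel), function(k) u8(dstart + k - 1L), 0L),
        "2"  = vapply(seq_len(nel),
                      function(k) i16(dstart + (k - 1L) * 2L), 0L),
        "4"  = vapply(seq_len(nel),
                      function(k) f32(dstart + (k - 1L) * 4L), 0),
        stop("unknown C3D parameter type ", etype))
      params[[paste0(id, "/", nm)]] <- list(value = val, dims = dims)
    }
    if (offset == 0L) break
    pos <- nxt
  }
  point_gid <- NULL
  for (gid in names(groups)) if (toupper(groups[[gid]]) == "POINT")
    point_gid <- gid
  if (is.null(point_gid)) stop("cannot read C3D file: no POINT group")
  getp <- function(nm) params[[paste0(point_gid, "/", nm)]]

  labels_p <- getp("LABELS")
  if (is.null(labels_p)) stop("cannot read C3D file: no POINT:LABELS")
  ld <- labels_p$dims
  lab_chars <- labels_p$value
  labels <- trimws(substring(lab_chars,
                             seq(1, by = ld[1], length.out = ld[2]),
                             seq(ld[1], by = ld[1], length.out = ld[2])))
  labels <- sub("^.*:", "", labels)   # strip subject prefixes
  used <- getp("USED");  if (!is.null(used)) n_points <- used$value[1]
  scale <- getp("SCALE"); scale <- if (is.null(scale)) hdr_scale else scale$value[1]
  rate <- getp("RATE");  if (!is.null(rate)) frame_rate <- rate$value[1]
  fr_p <- getp("FRAMES")
  nf <- if (!is.null(fr_p)) as.integer(fr_p$value[1]) else
    last_frame - first_frame + 1L
  ds_p <- getp("DATA_START"); if (!is.null(ds_p)) data_block <- ds_p$value[1]

  missing_mk <- setdiff(.GAIT_MARKERS, labels)
  if (length(missing_mk))
    stop("marker-set incomplete: missing ",
         paste(missing_mk, collapse = ", "))

  # --- 3D point data -------------------------------------------------------
  d0 <- (data_block - 1L) * 512L
  per_frame <- n_points * 4L
  if (scale < 0) {                       # floating-point storage
    need <- d0 + nf * per_frame * 4L
    if (length(raw) < need) stop("cannot read C3D file: data truncated")
    vals <- readBin(raw[(d0 + 1L):need], "double", size = 4,
                    n = nf * per_frame, endian = "little")
  } else {                               # signed-integer storage
    need <- d0 + nf * per_frame * 2L
    if (length(raw) < need) stop("cannot read C3D file: data truncated")
    vals <- readBin(raw[(d0 + 1L):need], "integer", size = 2,
                    n = nf * per_frame, endian = "little") * scale
  }
  arr <- array(vals, c(4L, n_points, nf))   # (xyzr, point, frame)
  pos3 <- aperm(arr[1:3, , , drop = FALSE], c(3, 2, 1))
  dimnames(pos3) <- list(NULL, labels[seq_len(n_points)], c("x", "y", "z"))
  pos3 <- pos3[, .GAIT_MARKERS, , drop = FALSE]
  gait_trial(pos3, frame_rate, patient_id = patient_id, form = form,
             trial_id = trial_id %||%
               sub("\\.[^.]*$", "", basename(path)))
}

#' Write a trial to a C3D file
#'
#' Emits an Intel-format C3D with floating-point point data and a POINT
#' group carrying USED, FRAMES, SCALE, RATE, DATA_START and LABELS, which
#' is sufficient for a lossless (within float32) round trip through
#' [read_c3d()].
#'
#' @param trial a [gait_trial()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  nf <- n_frames(trial)
  np <- 19L
  w8  <- function(x) as.raw(bitwAnd(as.integer(x), 255L))
  w16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
  wf32 <- function(x) writeBin(as.numeric(x), raw(), size = 4,
                               endian = "little")

  # parameter section: POINT group + 6 parameters
  lab_w <- 8L
  labels <- formatC(.GAIT_MARKERS, width = lab_w, flag = "-")
  gp <- function(name, desc = "") {       # group record, id -1
    c(w8(nchar(name)), w8(256L - 1L), charToRaw(name),
      w16(1L + nchar(desc)), w8(nchar(desc)),
      if (nchar(desc)) charToRaw(desc))
  }
  pr <- function(name, etype, dims, data_raw) {  # parameter record, group 1
    c(w8(nchar(name)), w8(1L), charToRaw(name),
      w16(3L + length(dims) + length(data_raw)),
      w8(if (etype < 0) 256L + etype else etype),
      w8(length(dims)), if (length(dims)) as.raw(dims),
      data_raw, w8(0L))
  }
  ps <- c(gp("POINT"),
          pr("USED", 2L, integer(0), w16(np)),
          pr("FRAMES", 2L, integer(0), w16(nf)),
          pr("SCALE", 4L, integer(0), wf32(-1)),
          pr("RATE", 4L, integer(0), wf32(trial$frame_rate)))
  # DATA_START depends on parameter-section length; labels are fixed size
  lab_rec <- pr("LABELS", -1L, c(lab_w, np),
                charToRaw(paste(labels, collapse = "")))
  n_param_bytes <- 4L + length(ps) + length(lab_rec) +
    length(pr("DATA_START", 2L, integer(0), w16(0L)))
  n_param_blocks <- as.integer(ceiling(n_param_bytes / 512))
  data_block <- 2L + n_param_blocks
  ps <- c(ps, pr("DATA_START", 2L, integer(0), w16(data_block)), lab_rec)
  param <- c(as.raw(c(0x01, 0x50)), w8(n_param_blocks), w8(84L), ps)
  param <- c(param, raw(n_param_blocks * 512L - length(param)))

  header <- c(w8(2L), w8(80L), w16(np), w16(0L), w16(1L), w16(nf),
              w16(10L), wf32(-1), w16(data_block), w16(0L),
              wf32(trial$frame_rate))
  header <- c(header, raw(512L - length(header)))

  flat <- aperm(trial$positions, c(3, 2, 1))      # (xyz, marker, frame)
  dat <- array(0, c(4L, np, nf))
  dat[1:3, , ] <- flat
  data_raw <- wf32(as.numeric(dat))

  writeBin(c(header, param, data_raw), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
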