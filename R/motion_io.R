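#' Read a marker trajectory from the flat CSV dialect
#'
#' The dialect is a plain UTF-8 CSV with LF line endings, `.` decimal
#' point, and header `frame,time_s,<marker>_x,<marker>_y,<marker>_z,...`:
#' `frame` is a contiguous 1-based integer, `time_s` the sample time in
#' seconds, and every marker contributes exactly three coordinate
#' columns. Malformed files are rejected with an error naming the
#' offending row or column; nothing is silently repaired.
#'
#' @param path File path.
#' @param units Length-unit label to attach (default `"mm"`).
#' @return A [marker_trajectory()]; the sampling rate is inferred from
#'   the median time step and checked for uniformity (1e-6 relative).
#' @export
read_markers_csv <- function(path, units = "mm") {
  if (!file.exists(path))
    mn_stop(paste0("no such file: ", path), "mn_parse_error")
  df <- read.csv(path, check.names = FALSE)
  cols <- names(df)
  if (length(cols) < 5L || cols[1] != "frame" || cols[2] != "time_s")
    mn_stop("header must start with 'frame,time_s'", "mn_parse_error")
  ccols <- cols[-(1:2)]
  hit <- regmatches(ccols, regexec("^(.*)_([xyz])$", ccols))
  bad <- which(lengths(hit) != 3L)
  if (length(bad))
    mn_stop(paste0("column '", ccols[bad[1]], "' is not <marker>_x/_y/_z"),
            "mn_parse_error")
  mk <- vapply(hit, `[`, character(1), 2)
  ax <- vapply(hit, `[`, character(1), 3)
  for (nm in unique(mk)) {
    have <- sort(ax[mk == nm])
    if (!identical(have, c("x", "y", "z")))
      mn_stop(sprintf("marker '%s' has columns for axes {%s}, need exactly x,y,z",
                      nm, paste(have, collapse = ",")), "mn_parse_error")
  }
  for (j in seq_along(cols)) {
    v <- df[[j]]
    if (!is.numeric(v))
      mn_stop(paste0("column '", cols[j], "' is not numeric"), "mn_parse_error")
    if (any(is.na(v)))
      mn_stop(sprintf("missing value in column '%s', row %d",
                      cols[j], which(is.na(v))[1]), "mn_parse_error")
  }
  if (!identical(as.integer(df$frame), seq_len(nrow(df))))
    mn_stop("frame numbers must be contiguous starting at 1", "mn_parse_error")
  if (any(diff(df$time_s) <= 0))
    mn_stop(sprintf("time_s not strictly increasing at row %d",
                    which(diff(df$time_s) <= 0)[1] + 1L), "mn_parse_error")
  coords <- lapply(unique(mk), function(nm)
    as.matrix(df[, paste0(nm, "_", c("x", "y", "z")), drop = FALSE]))
  names(coords) <- unique(mk)
  marker_trajectory(df$time_s, coords, units = units)
}

#' Write a marker trajectory in the flat CSV dialect
#'
#' Columns are emitted in deterministic order: markers sorted by name,
#' axes x, y, z within each marker. Values are written at full double
#' precision so a write/read round trip reproduces the trajectory.
#'
#' @param trajectory A [marker_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "marker_trajectory"))
  if (length(trajectory$markers) == 0L)
    mn_stop("trajectory has no markers", "mn_data_error")
  mks <- sort(trajectory$markers)
  header <- c("frame", "time_s",
              as.vector(t(outer(mks, c("x", "y", "z"), paste, sep = "_"))))
  K <- length(trajectory$times)
  M <- do.call(cbind, lapply(mks, function(nm) trajectory$coords[[nm]]))
  lines <- paste(seq_len(K), sprintf("%.15g", trajectory$times),
                 apply(M, 1, function(r) paste(sprintf("%.17g", r),
                                               collapse = ",")),
                 sep = ",")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), lines), con, sep = "\n")
  invisible(path)
}

#' Read a TRC motion-capture file
#'
#' Parses the standard tab-separated TRC v1.0 text layout
#' (`PathFileType` line, header fields including `DataRate`, `NumFrames`,
#' `NumMarkers`, `Units`, a marker-name row, an axis row, then data rows
#' `Frame# Time X1 Y1 Z1 ...`). Header counts are checked against the
#' data; mismatches are errors.
#'
#' @param path File path.
#' @return A [marker_trajectory()] with units from the `Units` field.
#' @export
read_trc <- function(path) {
  if (!file.exists(path))
    mn_stop(paste0("no such file: ", path), "mn_parse_error")
  lines <- readLines(path)
  if (length(lines) < 6L || !startsWith(lines[1], "PathFileType"))
    mn_stop("not a TRC file (missing PathFileType header)", "mn_parse_error")
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  if (length(vals) < length(keys)) vals <- c(vals, rep("", length(keys) - length(vals)))
  hdr <- setNames(as.list(vals[seq_along(keys)]), keys)
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    mn_stop(paste0("TRC header lacks field(s): ", paste(miss, collapse = ", ")),
            "mn_parse_error")
  rate <- as.numeric(hdr$DataRate)
  n_frames <- as.integer(hdr$NumFrames)
  n_markers <- as.integer(hdr$NumMarkers)
  units <- hdr$Units
  if (!nzchar(units)) mn_stop("TRC Units field is empty", "mn_parse_error")
  name_row <- strsplit(lines[4], "\t")[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[nzchar(marker_names)]
  if (length(marker_names) != n_markers)
    mn_stop(sprintf("TRC header declares %d markers but the name row lists %d",
                    n_markers, length(marker_names)), "mn_parse_error")
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != n_frames)
    mn_stop(sprintf("TRC header declares %d frames but %d data rows found",
                    n_frames, length(data_lines)), "mn_parse_error")
  vals <- lapply(data_lines, function(l) as.numeric(strsplit(l, "\t")[[1]]))
  ncol_need <- 2L + 3L * n_markers
  lens <- lengths(vals)
  if (any(lens != ncol_need))
    mn_stop(sprintf("TRC data row %d has %d fields, expected %d",
                    which(lens != ncol_need)[1], lens[lens != ncol_need][1],
                    ncol_need), "mn_parse_error")
  M <- do.call(rbind, vals)
  if (any(is.na(M)))
    mn_stop("TRC data contain non-numeric cells", "mn_parse_error")
  coords <- lapply(seq_len(n_markers), function(i)
    M[, 2L + (3L * (i - 1L) + 1L):(3L * i), drop = FALSE])
  names(coords) <- marker_names
  marker_trajectory(M[, 2], coords, rate = rate, units = units)
}

## ---- model file -----------------------------------------------------------

serialize_bank <- function(bank) {
  out <- unclass(bank)
  out
}

deserialize_bank <- function(x) {
  if (x$kind == "harmonic")
    oscillator_bank("harmonic", omega = as.numeric(x$omega),
                    p0 = as.numeric(x$p0))
  else
    oscillator_bank("nonlinear", z_c = as.numeric(x$z_c),
                    nonlinearity = x$nonlinearity,
                    duffing_a = x$duffing_a, duffing_b = x$duffing_b,
                    p0 = as.numeric(x$p0))
}

serialize_model <- function(model) {
  list(bank = serialize_bank(model$bank),
       basis = unclass(model$basis),
       W = model$W, channel_names = rownames(model$W),
       satellite_names = colnames(model$W),
       t0 = model$t0, units = model$units)
}

## rebuild a numeric matrix from its JSON row-list form
as_num_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
}

deserialize_model <- function(x) {
  basis <- x$basis
  centers <- if (!is.null(basis$centers)) as_num_matrix(basis$centers)
  b <- if (!is.null(basis$b)) as.numeric(basis$b)
  u <- if (!is.null(basis$u)) as.numeric(basis$u)
  basis <- basis_config(basis$family, n_m = as.integer(basis$n_m), b = b,
                        centers = centers, x0 = as.numeric(basis$x0), u = u,
                        intercept = isTRUE(basis$intercept))
  W <- as_num_matrix(x$W)
  dimnames(W) <- list(unlist(x$channel_names), unlist(x$satellite_names))
  rn <- rownames(W)
  channels <- data.frame(marker = sub("\\.[xyz]$", "", rn),
                         axis = sub("^.*\\.", "", rn),
                         stringsAsFactors = FALSE)
  structure(list(bank = deserialize_bank(x$bank), basis = basis, W = W,
                 channels = channels, t0 = as.numeric(x$t0),
                 units = x$units),
            class = "motion_model")
}

#' Save a fitted model (and optional segmentation or motion library)
#'
#' The model file is a structured JSON text document holding the
#' oscillator bank, basis configuration (including radial centers),
#' weight matrix keyed by marker/axis, and optionally the per-segment
#' models of a segmented fit or a motion library with its switching
#' parameters. Floats are written at full precision, so save/load round
#' trips are lossless well beyond 1e-12.
#'
#' @param model A `motion_model`, a `segmented_fit`, or a list with a
#'   `library` ([motion_library()]) and `switch` ([switching_module()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(format = "mocapnet-model", version = 1L)
  if (inherits(model, "motion_model")) {
    doc$type <- "single"
    doc$model <- serialize_model(model)
  } else if (inherits(model, "segmented_fit")) {
    doc$type <- "segmented"
    doc$boundaries <- model$boundaries
    doc$segments <- lapply(model$fits, function(f) serialize_model(f$model))
  } else if (is.list(model) && !is.null(model$library)) {
    doc$type <- "library"
    doc$anchors <- model$library$anchors
    doc$models <- lapply(model$library$models, serialize_model)
    if (!is.null(model$switch)) doc$switch <- unclass(model$switch)
  } else {
    mn_stop("unsupported model object", "mn_data_error")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a model file
#'
#' @param path Path to a file written by [write_model()].
#' @return A `motion_model`, a list of per-segment models (type
#'   `"segmented"`, with `boundaries`), or a list with `library` and
#'   `switch` (type `"library"`).
#' @export
read_model <- function(path) {
  if (!file.exists(path))
    mn_stop(paste0("no such file: ", path), "mn_parse_error")
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mocapnet-model"))
    mn_stop("not a mocapnet model file", "mn_parse_error")
  bank_nums <- function(x) lapply(x, function(v)
    if (is.list(v)) as.numeric(unlist(v)) else v)
  switch(as.character(doc$type),
    single = deserialize_model(lapply(doc$model, identity)),
    segmented = list(type = "segmented",
                     boundaries = as.integer(unlist(doc$boundaries)),
                     models = lapply(doc$segments, deserialize_model)),
    library = {
      models <- lapply(doc$models, deserialize_model)
      out <- list(type = "library",
                  library = motion_library(as.numeric(unlist(doc$anchors)),
                                           models))
      if (!is.null(doc$switch)) {
        s <- bank_nums(doc$switch)
        out$switch <- switching_module(s$a_tilde, s$b_tilde, s$h_tilde,
                                       s$h, s$kappa, s$lambda_bar, s$xi,
                                       s$sigmoid_kind)
      }
      out
    },
    mn_stop("unknown model file type", "mn_parse_error"))
}
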