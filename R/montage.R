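#' Regions of interest covered by the montage
#' @return Character vector of the six ROI labels.
#' @export
roi_names <- function() c("LSTG", "RSTG", "LIFG", "RIFG", "LMFG", "RMFG")

#' Build a source-detector montage
#'
#' Default mirrors the study montage: 60 long channels (~30 mm
#' source-detector separation, 10 per ROI over bilateral STG, IFG and MFG)
#' and 8 short channels (8 mm separation; two in each STG, one in each IFG
#' and MFG), which sample only extracerebral signal and serve as nuisance
#' regressors.
#'
#' @param long_per_roi Named integer vector: long channels per ROI.
#' @param short_per_roi Named integer vector: short channels per ROI.
#' @param long_mm,short_mm Source-detector distances in mm.
#' @return A data.frame of class `nirs_montage` with columns `channel`,
#'   `source`, `detector`, `distance_mm`, `roi`, `is_short`.
#' @export
make_montage <- function(long_per_roi = stats::setNames(rep(10L, 6), roi_names()),
                         short_per_roi = stats::setNames(c(2L, 2L, 1L, 1L, 1L, 1L),
                                                         roi_names()),
                         long_mm = 30, short_mm = 8) {
  stopifnot(all(long_per_roi >= 0), all(short_per_roi >= 0))
  rows <- list()
  src <- 0L; det <- 0L
  for (roi in names(long_per_roi)) {
    n <- long_per_roi[[roi]]
    if (n == 0) next
    for (k in seq_len(n)) {
      src <- src + 1L; det <- det + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, detector = det, distance_mm = long_mm, roi = roi,
        is_short = FALSE, stringsAsFactors = FALSE)
    }
  }
  for (roi in names(short_per_roi)) {
    n <- short_per_roi[[roi]]
    if (n == 0) next
    for (k in seq_len(n)) {
      src <- src + 1L; det <- det + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, detector = det, distance_mm = short_mm, roi = roi,
        is_short = TRUE, stringsAsFactors = FALSE)
    }
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = integer(0), detector = integer(0),
               distance_mm = numeric(0), roi = character(0),
               is_short = logical(0))
  m <- cbind(channel = sprintf("S%d_D%d", m$source, m$detector), m)
  bad <- setdiff(unique(m$roi[!m$is_short]), unique(m$roi[m$is_short]))
  if (length(bad))
    warning("ROI(s) without short channels (short-channel regression degrades): ",
            paste(bad, collapse = ", "))
  class(m) <- c("nirs_montage", "data.frame")
  m
}

#' Write / read a montage TSV
#' @param montage A `nirs_montage`.
#' @param path TSV path.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns
#'   the montage.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("channel", "source", "detector", "distance_mm", "roi", "is_short")
  if (!all(need %in% names(m)))
    stop("montage file missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "), call. = FALSE)
  class(m) <- c("nirs_montage", "data.frame")
  m
}
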