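# Extended 10-20 scalp montage (64 channels) with approximate 2D head
# coordinates. x < 0 is left, y > 0 is anterior; units are arbitrary head
# radii. Named electrodes from the analyses (Pz, CP1) are included. Four EOG
# channels record the horizontal/vertical electrooculogram of each eye.

montage_rows <- list(
  Fp = 4.0, AF = 3.2, F = 2.4, FT = 1.2, FC = 1.2, T = 0, C = 0,
  TP = -1.2, CP = -1.2, P = -2.4, PO = -3.2, O = -4.0, I = -4.6
)

#' Scalp montage for the simulator and ROI definitions
#'
#' @param n_channels number of scalp channels (default 64); smaller values take
#'   an evenly spaced subset that always retains Pz and CP1.
#' @return data frame with columns `name`, `x`, `y`, `eog` (logical). The four
#'   EOG channels (`EOG1`..`EOG4`) are appended after the scalp rows.
#' @export
build_montage <- function(n_channels = 64) {
  names64 <- c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "Iz")
  stopifnot(length(names64) == 64, n_channels >= 4, n_channels <= 64)
  coord <- function(nm) {
    row <- sub("^([A-Za-z]+?)[0-9z]+$", "\\1", nm)
    if (nm == "Iz") row <- "I"
    y <- montage_rows[[row]]
    suffix <- sub("^[A-Za-z]+?([0-9z]+)$", "\\1", nm)
    if (suffix == "z") {
      x <- 0
    } else {
      k <- as.integer(suffix)
      side <- if (k %% 2 == 1) -1 else 1
      x <- side * ceiling(k / 2) * 0.9
    }
    c(x = x, y = y)
  }
  xy <- t(vapply(names64, coord, c(x = 0, y = 0)))
  df <- data.frame(name = names64, x = xy[, "x"], y = xy[, "y"], eog = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (n_channels < 64) {
    keep <- unique(c(round(seq(1, 64, length.out = n_channels)),
                     match(c("Pz", "CP1"), names64)))
    keep <- sort(keep)[seq_len(n_channels)]
    if (!all(c("Pz", "CP1") %in% names64[keep])) {
      keep <- sort(unique(c(keep[seq_len(n_channels - 2)],
                            match(c("Pz", "CP1"), names64))))
    }
    df <- df[keep, , drop = FALSE]
  }
  eog <- data.frame(name = paste0("EOG", 1:4), x = c(-2.5, 2.5, -1.5, 1.5),
                    y = c(4.5, 4.5, 4.8, 4.8), eog = TRUE,
                    stringsAsFactors = FALSE)
  out <- rbind(df, eog)
  rownames(out) <- NULL
  out
}

#' Assign scalp electrodes to quadrant regions of interest
#'
#' Hemisphere is the sign of `x`, anterior/posterior the sign of `y`; midline
#' electrodes (`x == 0`) and the central row (`y == 0`) are excluded.
#'
#' @param montage data frame from [build_montage()].
#' @return character vector per scalp channel: `"left_anterior"`,
#'   `"left_posterior"`, `"right_anterior"`, `"right_posterior"`, or `NA` for
#'   excluded electrodes; named by channel.
#' @export
montage_rois <- function(montage) {
  m <- montage[!montage$eog, , drop = FALSE]
  roi <- rep(NA_character_, nrow(m))
  lr <- ifelse(m$x < 0, "left", ifelse(m$x > 0, "right", NA))
  ap <- ifelse(m$y > 0, "anterior", ifelse(m$y < 0, "posterior", NA))
  ok <- !is.na(lr) & !is.na(ap)
  roi[ok] <- paste(lr[ok], ap[ok], sep = "_")
  stats::setNames(roi, m$name)
}

#' Approximate EGI-64 to 10-20 channel name map
#'
#' Convenience lookup for ingesting recordings whose channels are labelled
#' `E1`..`E64` (64-channel geodesic nets). The correspondence is positional
#' and approximate -- it pairs each numbered electrode with the extended
#' 10-20 name at a similar scalp location in this package's montage -- and is
#' intended only to let such recordings flow through analyses that refer to
#' named electrodes (Pz, CP1). Verify against the net's technical layout
#' before using it for spatial claims.
#'
#' @return data frame with columns `egi` (`E1`..`E64`) and `name`.
#' @export
egi64_name_map <- function() {
  m <- build_montage(64)
  data.frame(egi = paste0("E", 1:64), name = m$name[!m$eog],
             stringsAsFactors = FALSE)
}

# gaussian spatial profile centred on a montage location
spatial_profile <- function(montage, center, width = 1.6) {
  m <- montage[!montage$eog, , drop = FALSE]
  cx <- m$x[m$name == center]
  cy <- m$y[m$name == center]
  if (length(cx) == 0) {  # fall back to posterior midline
    cx <- 0; cy <- -2.4
  }
  w <- exp(-((m$x - cx)^2 + (m$y - cy)^2) / (2 * width^2))
  stats::setNames(w / max(w), m$name)
}
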