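#' Electrode montages and source topographies
#'
#' Channel bookkeeping in 10-10 nomenclature. The full montage has 64
#' channels and contains the 30-electrode posterior region of interest
#' (centro-parietal, temporo-parietal, parietal, parieto-occipital and
#' occipital) over which certainty effects are modelled. Reduced montages
#' (32, 16 channels) keep a representative posterior subset and exist so
#' simulation-heavy tests can scale down.
#'
#' @name montage
NULL

.roi30 <- c("CPz", paste0("CP", 1:6),
            paste0("TP", 7:10),
            "Pz", paste0("P", 1:8),
            "POz", "PO3", "PO4", paste0("PO", 7:10),
            "Oz", "O1", "O2")

.montage64 <- c(
  # 34 anterior/central channels
  "Fp1", "Fp2", "AFz", "AF3", "AF4", "AF7", "AF8",
  "Fz", paste0("F", 1:8),
  "FCz", paste0("FC", 1:6), "FT7", "FT8",
  "Cz", paste0("C", 1:6), "T7", "T8",
  # 30 posterior ROI channels
  .roi30)

.montage32 <- c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8",
                "FC1", "FC2", "Cz", "C3", "C4",
                "CPz", "CP1", "CP2", "CP5", "CP6", "TP7", "TP8",
                "Pz", "P3", "P4", "P7", "P8",
                "POz", "PO3", "PO4", "PO7", "PO8", "Oz", "O1", "O2")

.montage16 <- c("Fz", "F3", "F4", "FC1", "FC2", "Cz", "C3", "C4",
                "CPz", "Pz", "P3", "P4", "POz", "Oz", "O1", "O2")

#' Channel labels for a montage
#'
#' @param n_channels 64 (default), 32 or 16.
#' @return character vector of channel labels.
#' @export
hft_montage <- function(n_channels = 64L) {
  switch(as.character(n_channels),
         "64" = .montage64, "32" = .montage32, "16" = .montage16,
         stop("supported montages: 64, 32, 16 channels"))
}

#' The 30-electrode posterior region of interest
#'
#' @return character vector of the 30 posterior channel labels.
#' @export
posterior_roi <- function() .roi30

channel_region <- function(labels) {
  reg <- rep("anterior", length(labels))
  reg[labels %in% c("Oz", "O1", "O2")] <- "occipital"
  reg[grepl("^PO", labels)] <- "parieto-occipital"
  reg[grepl("^P[0-9z]", labels)] <- "parietal"
  reg[grepl("^CP", labels)] <- "centro-parietal"
  reg[grepl("^TP", labels)] <- "temporo-parietal"
  reg
}

#' Source-to-channel mixing weights
#'
#' Smooth region-wise gain profiles for the three simulated sources:
#' the bottom-up (contrast-driven) and interaction sources are strongest
#' over occipital channels, the top-down (semantic) source over
#' temporo-parietal and centro-parietal channels, mirroring the scalp
#' distributions typical of contrast tagging versus semantic tagging. The
#' interaction profile is deliberately close to (but not identical with)
#' the bottom-up profile.
#'
#' @param labels channel labels (e.g. from [hft_montage()]).
#' @return matrix `length(labels)` x 3 with columns `bottom_up`,
#'   `top_down`, `interaction`.
#' @export
source_topography <- function(labels) {
  reg <- channel_region(labels)
  # dipolar profiles (posterior positivity, frontal negativity) so that
  # average referencing removes little of the signal of interest
  bu <- c(occipital = 1, "parieto-occipital" = 0.85, parietal = 0.5,
          "centro-parietal" = 0.2, "temporo-parietal" = 0.1,
          anterior = -0.35)
  td <- c(occipital = 0.15, "parieto-occipital" = 0.3, parietal = 0.6,
          "centro-parietal" = 0.85, "temporo-parietal" = 1,
          anterior = -0.5)
  ia <- c(occipital = 1, "parieto-occipital" = 0.8, parietal = 0.45,
          "centro-parietal" = 0.15, "temporo-parietal" = 0.05,
          anterior = -0.3)
  w <- cbind(bottom_up = bu[reg], top_down = td[reg], interaction = ia[reg])
  rownames(w) <- labels
  w
}
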