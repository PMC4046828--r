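# Expression-trend classification of five-stage TPM profiles into the four
# canonical ripening groups: up-regulated, down-regulated, low-high-low, and
# constitutive. Rule thresholds were calibrated once against the published
# reference profiles of 39 representative ripening genes (shipped in
# inst/extdata/ripening_profiles.tsv) and are frozen as defaults.

#' Classify a five-stage expression profile
#'
#' Ordered decision rules on the profile floored at TPM 0.001, with
#' amplitude \code{a = max/min}, Spearman correlation \code{rho} of the
#' profile with the stage index (average ranks for ties), and the middle
#' stage value \code{v3}:
#' \enumerate{
#'   \item constitutive if \code{a < amplitude_min}, unless the profile shows
#'     a strong monotone trend (\code{|rho| >= rho_strong} with
#'     \code{a >= trend_escape_amplitude}) — modest-amplitude but steadily
#'     trending genes are not flat;
#'   \item low-high-low if \code{v3} is the unique maximum and
#'     \code{v3 >= mid_peak_ratio * max(v1, v5)};
#'   \item up if \code{rho >= rho_strong} or (\code{v5} is the maximum and
#'     \code{v5 >= end_ratio * v1});
#'   \item down if \code{rho <= -rho_strong} or (\code{v1} is the maximum and
#'     \code{v1 >= end_ratio * v5});
#'   \item otherwise unclassified.
#' }
#' Rank-correlation comparisons use a 1e-9 tolerance so profiles sitting
#' exactly on the rho boundary are not lost to floating point.
#'
#' @param profile numeric vector of 5 non-negative TPM values (stages 1..5).
#' @param amplitude_min constitutive ceiling on max/min (default 4).
#' @param rho_strong Spearman threshold for a monotone trend (default 0.6).
#' @param mid_peak_ratio required excess of the stage-3 peak over the
#'   endpoints (default 1.3).
#' @param end_ratio required endpoint fold change for the max-endpoint rules
#'   (default 2).
#' @param trend_escape_amplitude minimum amplitude for the strong-trend
#'   escape from the constitutive rule (default 2).
#' @return List of class \code{dge_pattern}: \code{group} (one of
#'   \code{I_up}, \code{II_down}, \code{III_low_high_low},
#'   \code{IV_constitutive}, \code{unclassified}), \code{amplitude},
#'   \code{rho}, \code{peak_stage}.
#' @export
classify_pattern <- function(profile, amplitude_min = 4, rho_strong = 0.6,
                             mid_peak_ratio = 1.3, end_ratio = 2,
                             trend_escape_amplitude = 2) {
  if (length(profile) != 5L) stop("profile must have exactly 5 stages", call. = FALSE)
  if (any(is.na(profile)) || any(profile < 0))
    stop("profile must be non-negative TPM values", call. = FALSE)
  eps <- 1e-9
  v <- pmax(profile, 0.001)
  a <- max(v) / min(v)
  rho <- if (stats::sd(v) == 0) 0 else
    suppressWarnings(cor(v, seq_along(v), method = "spearman"))
  peak <- which.max(v)
  strong_trend <- abs(rho) >= rho_strong - eps && a >= trend_escape_amplitude
  group <-
    if (a < amplitude_min && !strong_trend) {
      "IV_constitutive"
    } else if (v[3L] == max(v) && sum(v == max(v)) == 1L &&
               v[3L] >= mid_peak_ratio * max(v[1L], v[5L])) {
      "III_low_high_low"
    } else if (rho >= rho_strong - eps ||
               (v[5L] == max(v) && v[5L] >= end_ratio * v[1L])) {
      "I_up"
    } else if (rho <= -(rho_strong - eps) ||
               (v[1L] == max(v) && v[1L] >= end_ratio * v[5L])) {
      "II_down"
    } else {
      "unclassified"
    }
  structure(list(group = group, amplitude = a, rho = rho,
                 peak_stage = as.integer(peak)),
            class = "dge_pattern")
}

#' @export
print.dge_pattern <- function(x, ...) {
  cat(sprintf("%s (amplitude %.2f, rho %.2f, peak stage %d)\n",
              x$group, x$amplitude, x$rho, x$peak_stage))
  invisible(x)
}

#' Classify every row of a TPM profile matrix
#'
#' @param tpm matrix or data.frame with 5 columns (stages) and gene rownames.
#' @param ... passed to \code{\link{classify_pattern}}.
#' @return data.frame: \code{gene_id}, \code{group}, \code{amplitude},
#'   \code{rho}, \code{peak_stage}.
#' @export
classify_patterns <- function(tpm, ...) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) != 5L) stop("profile matrix must have 5 stage columns", call. = FALSE)
  res <- apply(tpm, 1L, function(v) {
    p <- classify_pattern(as.numeric(v), ...)
    c(group = p$group, amplitude = p$amplitude, rho = p$rho,
      peak_stage = p$peak_stage)
  })
  data.frame(
    gene_id = if (is.null(rownames(tpm))) as.character(seq_len(ncol(res))) else rownames(tpm),
    group = unname(res["group", ]),
    amplitude = as.numeric(res["amplitude", ]),
    rho = as.numeric(res["rho", ]),
    peak_stage = as.integer(res["peak_stage", ]),
    stringsAsFactors = FALSE
  )
}

#' Reference ripening profiles
#'
#' Loads the bundled TPM profiles of 39 representative pear-fruit ripening
#' genes across five developmental stages, together with their published
#' trend group, used to calibrate and validate the pattern classifier.
#'
#' @return data.frame: \code{gene_id}, \code{annotation}, \code{group},
#'   \code{FS1}..\code{FS5}.
#' @export
ripening_profiles <- function() {
  path <- system.file("extdata", "ripening_profiles.tsv", package = "tagdge",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
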