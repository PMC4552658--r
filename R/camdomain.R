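#' Hydrophobicity scales for helical-wheel analysis
#'
#' Named residue hydrophobicity scales available to
#' [hydrophobic_moment()] and [scan_amphiphilicity()]. `"eisenberg"` is the
#' Eisenberg consensus scale, the conventional choice for hydrophobic-moment
#' work; `"kyte-doolittle"` is provided as an alternative.
#'
#' @return Named list of named numeric vectors (one value per standard
#'   amino-acid letter).
#' @export
hydrophobicity_scales <- function() {
  list(
    eisenberg = c(
      A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
      Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
      L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
      S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
    `kyte-doolittle` = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
      L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  )
}

get_scale <- function(scale) {
  scales <- hydrophobicity_scales()
  if (!is.character(scale) || length(scale) != 1L || !scale %in% names(scales)) {
    stop("unknown hydrophobicity scale; available: ",
         paste(names(scales), collapse = ", "), call. = FALSE)
  }
  scales[[scale]]
}

split_residues <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(unique(res), names(hydrophobicity_scales()$eisenberg))
  if (length(bad) > 0L) {
    stop("non-standard residue(s) in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res
}

#' Helical-wheel coordinates of a peptide
#'
#' Places residue n (0-based) at angle n * `angle_per_residue` on the unit
#' circle, the construction behind a helical wheel projection (100 degrees
#' per residue for an ideal alpha helix: 3.6 residues per turn).
#'
#' @param sequence Peptide as a single string of standard one-letter codes.
#' @param angle_per_residue Rotation per residue, degrees. Default 100.
#' @return `data.frame` with columns `index` (1-based), `residue`,
#'   `angle_deg` (reduced modulo 360), `x`, `y`.
#' @examples
#' wheel_coordinates("LKKLLKLLKKLLKLLKKL")
#' @export
wheel_coordinates <- function(sequence, angle_per_residue = 100) {
  res <- split_residues(sequence)
  n <- seq_along(res) - 1L
  ang <- (n * angle_per_residue) %% 360
  rad <- ang * pi / 180
  data.frame(index = n + 1L, residue = res, angle_deg = ang,
             x = cos(rad), y = sin(rad))
}

#' Mean helical hydrophobic moment
#'
#' The Eisenberg hydrophobic moment of a window, normalised by its length:
#' \deqn{\mu_H = \frac{1}{N}\left|\sum_{n=0}^{N-1} h_n e^{i n \delta}\right|}
#' with \eqn{\delta} the helical rotation per residue. A large mean moment
#' marks a helix whose hydrophobic residues cluster on one face, the
#' geometric signature of an amphiphilic (e.g. calmodulin-binding) helix.
#' The value is invariant under a global rotation of the wheel.
#'
#' @inheritParams wheel_coordinates
#' @param scale Name of a scale from [hydrophobicity_scales()].
#' @return Mean hydrophobic moment (dimensionless, >= 0).
#' @examples
#' hydrophobic_moment(strrep("A", 18))   # exactly 0: 5 full turns
#' hydrophobic_moment("LKKLLKLLKKLLKLLKKL")
#' @export
hydrophobic_moment <- function(sequence, angle_per_residue = 100,
                               scale = "eisenberg") {
  h <- get_scale(scale)[split_residues(sequence)]
  n <- seq_along(h) - 1L
  delta <- angle_per_residue * pi / 180
  sqrt(sum(h * cos(n * delta))^2 + sum(h * sin(n * delta))^2) / length(h)
}

net_charge_neutral_ph <- function(residues) {
  # simplification used throughout: K, R = +1; D, E = -1; H = 0
  sum(residues %in% c("K", "R")) - sum(residues %in% c("D", "E"))
}

#' Sliding-window amphiphilicity scan of a protein
#'
#' Slides a window (default 18 residues, five helical turns) along the
#' protein with stride 1 and scores each window's mean hydrophobic moment,
#' mean hydrophobicity and net charge at neutral pH. This reproduces
#' computationally what a helical-wheel projection shows visually, and is
#' the screen used to delineate a candidate calmodulin-binding domain
#' (for AtCyp19-3: an amphiphilic stretch within residues 35-70 of the
#' N-terminus).
#'
#' @param protein Protein sequence as a single string (1-based residue
#'   coordinates throughout).
#' @param window Window length in residues; `protein` must be at least this
#'   long. Default 18.
#' @inheritParams hydrophobic_moment
#' @param roi Optional length-2 integer vector `c(start, end)` (1-based,
#'   inclusive) of a region of interest; the result then reports whether the
#'   maximal-moment window overlaps it.
#' @return Object of class `helix_scan`: a `data.frame` with one row per
#'   window (`start`, `end`, `sequence`, `muH`, `meanH`, `net_charge`) and
#'   attributes `best` (row index of the maximal `muH` window) and, when
#'   `roi` is given, `best_in_roi`.
#' @examples
#' prot <- paste0(strrep("S", 34), "LKKLLKLLKKLLKLLKKL", strrep("S", 10))
#' sc <- scan_amphiphilicity(prot, roi = c(35, 52))
#' sc[attr(sc, "best"), ]
#' @export
scan_amphiphilicity <- function(protein, window = 18L,
                                angle_per_residue = 100,
                                scale = "eisenberg", roi = NULL) {
  res <- split_residues(protein)
  len <- length(res)
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2 residues", call. = FALSE)
  if (len < window) {
    stop(sprintf("sequence (%d aa) is shorter than the window (%d aa)",
                 len, window), call. = FALSE)
  }
  h_scale <- get_scale(scale)
  delta <- angle_per_residue * pi / 180
  starts <- seq_len(len - window + 1L)
  rows <- lapply(starts, function(s) {
    win <- res[s:(s + window - 1L)]
    h <- h_scale[win]
    n <- seq_along(h) - 1L
    data.frame(
      start = s, end = s + window - 1L,
      sequence = paste(win, collapse = ""),
      muH = sqrt(sum(h * cos(n * delta))^2 + sum(h * sin(n * delta))^2) /
        window,
      mean_h = mean(h),
      net_charge = net_charge_neutral_ph(win))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_h"] <- "meanH"
  best <- which.max(out$muH)
  attr(out, "best") <- best
  if (!is.null(roi)) {
    if (length(roi) != 2L || roi[1L] > roi[2L]) {
      stop("roi must be c(start, end) with start <= end", call. = FALSE)
    }
    attr(out, "roi") <- as.integer(roi)
    attr(out, "best_in_roi") <-
      out$start[best] <= roi[2L] && out$end[best] >= roi[1L]
  }
  class(out) <- c("helix_scan", "data.frame")
  out
}

#' @export
print.helix_scan <- function(x, ...) {
  best <- attr(x, "best")
  cat(sprintf("Amphiphilicity scan: %d windows of %d residues\n",
              nrow(x), x$end[1L] - x$start[1L] + 1L))
  cat(sprintf("  max muH = %.4f at residues %d-%d (%s)\n",
              x$muH[best], x$start[best], x$end[best], x$sequence[best]))
  if (!is.null(attr(x, "roi"))) {
    roi <- attr(x, "roi")
    cat(sprintf("  region of interest %d-%d: best window %s\n",
                roi[1L], roi[2L],
                if (attr(x, "best_in_roi")) "overlaps" else "does not overlap"))
  }
  invisible(x)
}

#' Scan every record of a FASTA file for amphiphilic windows
#'
#' @param path Path to a (multi-record) protein FASTA file.
#' @inheritParams scan_amphiphilicity
#' @return `data.frame` with a leading `record` column and one row per
#'   window per record.
#' @export
scan_fasta <- function(path, window = 18L, angle_per_residue = 100,
                       scale = "eisenberg", roi = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  out <- lapply(seq_along(seqs), function(i) {
    sc <- scan_amphiphilicity(as.character(seqs[[i]]), window = window,
                              angle_per_residue = angle_per_residue,
                              scale = scale, roi = roi)
    cbind(record = names(seqs)[i], as.data.frame(sc))
  })
  do.call(rbind, out)
}
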