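# Template MIR/NBR definitions and their transfer to family members
# through an alignment map, plus boundary-perturbation controls and the
# N-terminal amphipathic helix and charge-density helpers.

#' Construct a region annotation
#'
#' Partitions a domain range into membrane-interaction regions (MIR) and
#' their complement, the non-binding regions (NBR).
#'
#' @param domain_range closed interval \code{c(start, end)}.
#' @param mir_intervals interval matrix (see \code{\link{intervals}}),
#'   sorted, disjoint, contained in \code{domain_range}.
#' @return object of class \code{RegionAnnotation} with \code{domain_range},
#'   \code{mir_intervals} and the derived \code{nbr_intervals}.
#' @export
region_annotation <- function(domain_range, mir_intervals = intervals()) {
  domain_range <- as.integer(domain_range)
  mir_intervals <- iv_validate(mir_intervals, domain_range, "MIR")
  structure(list(domain_range = domain_range,
                 mir_intervals = mir_intervals,
                 nbr_intervals = complement_regions(domain_range,
                                                    mir_intervals)),
            class = "RegionAnnotation")
}

#' @export
print.RegionAnnotation <- function(x, ...) {
  fmt <- function(iv) if (nrow(iv) == 0L) "-" else
    paste(sprintf("[%d,%d]", iv[, "start"], iv[, "end"]), collapse = " ")
  cat("RegionAnnotation on [", x$domain_range[1], ",", x$domain_range[2],
      "]\n  MIR: ", fmt(x$mir_intervals), "\n  NBR: ", fmt(x$nbr_intervals),
      "\n", sep = "")
  invisible(x)
}

#' Complement of the MIR intervals within the domain range
#'
#' @param domain_range closed interval \code{c(start, end)}.
#' @param mir_intervals sorted disjoint interval matrix inside the range.
#' @return interval matrix of the NBR (sorted, disjoint).
#' @export
complement_regions <- function(domain_range, mir_intervals) {
  domain_range <- as.integer(domain_range)
  iv_validate(mir_intervals, domain_range, "MIR")
  pos <- domain_range[1]:domain_range[2]
  iv_from_positions(pos[!iv_contains(mir_intervals, pos)])
}

# per-residue region labels over the domain range ("MIR"/"NBR")
region_labels <- function(ann) {
  pos <- ann$domain_range[1]:ann$domain_range[2]
  ifelse(iv_contains(ann$mir_intervals, pos), "MIR", "NBR")
}

#' Transfer a template's MIR/NBR annotation to a target domain
#'
#' Target residues aligned to a template MIR residue become MIR; aligned to
#' an NBR residue, NBR. Unaligned target residues between mapped neighbours
#' (insertions) become MIR only when both nearest aligned flanking residues
#' are MIR — an insertion inside a membrane-binding surface most plausibly
#' stays on that surface — and NBR otherwise (including at a MIR/NBR
#' boundary). The target domain range is the span of the mapped positions.
#'
#' @param template list with \code{record} (\code{DomainRecord}) and
#'   \code{annotation} (\code{RegionAnnotation}), or a
#'   \code{RegionAnnotation} alone.
#' @param target target \code{DomainRecord} (used for bounds checking).
#' @param map \code{AlignmentMap} whose \code{pairs} connect template
#'   (column 1) to target (column 2) full-length positions.
#' @return \code{RegionAnnotation} on the target; per-residue transfer
#'   provenance is attached as attribute \code{provenance} (values
#'   \code{"aligned"} / \code{"insertion"}).
#' @export
transfer_annotation <- function(template, target, map) {
  ann <- if (inherits(template, "RegionAnnotation")) template
         else template$annotation
  pairs <- map$pairs
  dr <- ann$domain_range
  inside <- pairs[, 1] >= dr[1] & pairs[, 1] <= dr[2]
  pairs <- pairs[inside, , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("alignment has no pairs inside the template domain range")
  tpl_is_mir <- iv_contains(ann$mir_intervals, pairs[, 1])
  t_range <- c(min(pairs[, 2]), max(pairs[, 2]))
  pos <- t_range[1]:t_range[2]
  lab <- rep(NA_character_, length(pos))
  prov <- rep("insertion", length(pos))
  idx <- pairs[, 2] - t_range[1] + 1L
  lab[idx] <- ifelse(tpl_is_mir, "MIR", "NBR")
  prov[idx] <- "aligned"
  # insertions: MIR iff both nearest aligned flanking residues are MIR
  if (anyNA(lab)) {
    mapped_idx <- which(!is.na(lab))
    for (g in which(is.na(lab))) {
      left <- mapped_idx[mapped_idx < g]
      right <- mapped_idx[mapped_idx > g]
      left_lab <- if (length(left)) lab[max(left)] else "NBR"
      right_lab <- if (length(right)) lab[min(right)] else "NBR"
      lab[g] <- if (left_lab == "MIR" && right_lab == "MIR") "MIR" else "NBR"
    }
  }
  out <- region_annotation(t_range, iv_from_positions(pos[lab == "MIR"]))
  attr(out, "provenance") <- setNames(prov, pos)
  out
}

#' Expand or contract MIR boundaries
#'
#' Control for annotation-boundary uncertainty: every MIR interval is grown
#' (\code{delta > 0}) or shrunk (\code{delta < 0}) by \code{|delta|}
#' residues on both ends, clipped to the domain range; grown intervals that
#' meet are merged and intervals shrunk to nothing are removed. The NBR is
#' recomputed. Deltas beyond the validated \code{-2..+2} range error unless
#' \code{force = TRUE}.
#'
#' @param ann \code{RegionAnnotation}.
#' @param delta integer in \code{-2..+2}.
#' @param force allow larger \code{|delta|}.
#' @return adjusted \code{RegionAnnotation}.
#' @export
adjust_boundaries <- function(ann, delta, force = FALSE) {
  delta <- as.integer(delta)
  if (abs(delta) > 2L && !force)
    stop("|delta| > 2 is outside the validated range (use force = TRUE)")
  if (delta == 0L || nrow(ann$mir_intervals) == 0L)
    return(region_annotation(ann$domain_range, ann$mir_intervals))
  iv <- ann$mir_intervals
  s <- iv[, "start"] - delta
  e <- iv[, "end"] + delta
  keep <- e >= s
  s <- pmax(s[keep], ann$domain_range[1])
  e <- pmin(e[keep], ann$domain_range[2])
  keep2 <- e >= s
  iv2 <- intervals(s[keep2], e[keep2])
  if (nrow(iv2) > 1L) iv2 <- iv_merge_overlaps(iv2)
  region_annotation(ann$domain_range, iv2)
}

# Eisenberg consensus hydrophobicity scale
EISENBERG <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
               Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
               L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
               S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08,
               X = 0)

#' Mean hydrophobic moment of a peptide
#'
#' \eqn{\mu_H = |\sum_n H_n e^{i n \delta}| / N} with the Eisenberg
#' consensus scale and the helical twist \eqn{\delta} (default 100 degrees
#' per residue).
#'
#' @param peptide amino-acid string.
#' @param angle_deg twist per residue (degrees).
#' @return mean hydrophobic moment (per residue).
#' @export
hydrophobic_moment <- function(peptide, angle_deg = 100) {
  h <- EISENBERG[strsplit(peptide, "")[[1]]]
  n <- seq_along(h) - 1
  th <- n * angle_deg * pi / 180
  sqrt(sum(h * cos(th))^2 + sum(h * sin(th))^2) / length(h)
}

#' Detect a putative N-terminal amphipathic helix (H0)
#'
#' N-BAR domains carry an N-terminal amphipathic helix that is membrane
#' embedded in situ but often unresolved in crystal structures; it is
#' treated as membrane-binding. The stretch upstream of the domain
#' (positions \code{1..domain_start-1}) is scanned with a sliding window of
#' the mean hydrophobic moment (100 degrees/residue, Eisenberg consensus
#' scale); the maximal run of windows at or above the threshold is returned
#' as the putative H0 interval. Curated per-protein H0 ranges in the region
#' config take precedence over this detector.
#'
#' @param sequence full-length protein sequence.
#' @param domain_start first position of the structured domain.
#' @param window window length in residues (default 11).
#' @param threshold minimum mean moment per residue (default 0.25).
#' @param angle_deg twist per residue (degrees, default 100).
#' @return closed interval \code{c(start, end)} or \code{NULL}.
#' @export
detect_nterm_helix <- function(sequence, domain_start, window = 11,
                               threshold = 0.25, angle_deg = 100) {
  nterm_len <- domain_start - 1L
  if (nterm_len < window) return(NULL)
  starts <- seq_len(nterm_len - window + 1L)
  mu <- vapply(starts, function(s)
    hydrophobic_moment(substr(sequence, s, s + window - 1L), angle_deg),
    numeric(1))
  ok <- mu >= threshold
  if (!any(ok)) return(NULL)
  runs <- rle(ok)
  ends_r <- cumsum(runs$lengths)
  starts_r <- ends_r - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  first_w <- starts_r[best]; last_w <- ends_r[best]
  c(starts[first_w], starts[last_w] + window - 1L)
}

#' Basic-residue (K+R) density per region
#'
#' Charge-density check used to sanity-check MIR definitions: membrane
#' interaction surfaces of these families are lysine/arginine rich.
#'
#' @param sequence full-length protein sequence.
#' @param ann \code{RegionAnnotation}.
#' @return named numeric vector: fraction of K/R residues in \code{mir} and
#'   \code{nbr} (NaN for an empty region).
#' @export
region_charge_density <- function(sequence, ann) {
  dens <- function(iv) {
    pos <- iv_positions(iv)
    if (length(pos) == 0L) return(NaN)
    letters <- substring(sequence, pos, pos)
    mean(letters %in% c("K", "R"))
  }
  c(mir = dens(ann$mir_intervals), nbr = dens(ann$nbr_intervals))
}

#' Serialize region annotations to a BED-like TSV
#'
#' One row per interval with columns \code{protein_id}, \code{start},
#' \code{end}, \code{region} (MIR/NBR), \code{provenance}; the first line
#' is a comment declaring \code{coords: 1-based-closed}.
#'
#' @param annotations named list of \code{RegionAnnotation} (names are
#'   protein ids).
#' @param path output TSV.
#' @param provenance character note written on every row.
#' @export
write_regions_tsv <- function(annotations, path, provenance = "") {
  rows <- do.call(rbind, lapply(names(annotations), function(id) {
    ann <- annotations[[id]]
    rbind(
      if (nrow(ann$mir_intervals)) data.frame(
        protein_id = id, start = ann$mir_intervals[, "start"],
        end = ann$mir_intervals[, "end"], region = "MIR",
        provenance = provenance),
      if (nrow(ann$nbr_intervals)) data.frame(
        protein_id = id, start = ann$nbr_intervals[, "start"],
        end = ann$nbr_intervals[, "end"], region = "NBR",
        provenance = provenance))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coords: 1-based-closed", con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
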