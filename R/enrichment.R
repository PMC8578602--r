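# Region-wise acetylation tallies, enrichment frequencies and ratios,
# domain classification, family aggregation, boundary-sensitivity sweep and
# an optional permutation significance check.

#' Map acetylation sites onto a domain's regions
#'
#' Sites of the record's protein are checked against the sequence: a site
#' whose stated residue disagrees with the sequence letter at that position,
#' or that sits on a non-lysine, is quarantined with a reason rather than
#' silently dropped. Valid sites inside the domain range are flagged; valid
#' sites outside the domain range are tallied separately.
#'
#' @param record \code{DomainRecord}.
#' @param ann \code{RegionAnnotation} for the record.
#' @param sites \code{AcetylationSiteTable} (any proteins; filtered by id).
#' @return list: \code{acetyl_pos} (flagged in-domain positions),
#'   \code{outside_pos}, \code{quarantined} (data.frame position/reason),
#'   \code{n_input} (site rows for this protein).
#' @export
map_sites_to_domain <- function(record, ann, sites) {
  s <- sites[sites$protein_id == record$protein_id, , drop = FALSE]
  n_input <- nrow(s)
  acetyl <- integer(); outside <- integer()
  q_pos <- integer(); q_reason <- character()
  seq_len_full <- nchar(record$sequence)
  for (r in seq_len(n_input)) {
    p <- s$position[r]
    if (p > seq_len_full) {
      q_pos <- c(q_pos, p); q_reason <- c(q_reason, "position beyond sequence")
      next
    }
    letter <- substr(record$sequence, p, p)
    if (letter != s$residue[r]) {
      q_pos <- c(q_pos, p)
      q_reason <- c(q_reason, sprintf("residue mismatch (table %s, sequence %s)",
                                      s$residue[r], letter))
      next
    }
    if (letter != "K") {
      q_pos <- c(q_pos, p); q_reason <- c(q_reason, "non-lysine position")
      next
    }
    if (p >= ann$domain_range[1] && p <= ann$domain_range[2])
      acetyl <- c(acetyl, p)
    else outside <- c(outside, p)
  }
  list(acetyl_pos = sort(acetyl), outside_pos = sort(outside),
       quarantined = data.frame(position = q_pos, reason = q_reason),
       n_input = n_input)
}

#' Tally residues, lysines and acetyl-lysines per region
#'
#' @param record \code{DomainRecord}.
#' @param ann \code{RegionAnnotation}.
#' @param flags result of \code{\link{map_sites_to_domain}}.
#' @return object of class \code{RegionCounts}: data.frame with rows MIR
#'   and NBR and columns \code{n_residues}, \code{n_lysines}, \code{n_ack}.
#' @export
count_regions <- function(record, ann, flags) {
  count_one <- function(iv) {
    pos <- iv_positions(iv)
    letters <- if (length(pos)) substring(record$sequence, pos, pos)
               else character()
    c(n_residues = length(pos),
      n_lysines = sum(letters == "K"),
      n_ack = sum(flags$acetyl_pos %in% pos))
  }
  out <- as.data.frame(rbind(MIR = count_one(ann$mir_intervals),
                             NBR = count_one(ann$nbr_intervals)))
  out$region <- rownames(out)
  class(out) <- c("RegionCounts", "data.frame")
  out
}

region_counts <- function(mir, nbr) {
  # mir/nbr: c(n_residues, n_lysines, n_ack)
  out <- as.data.frame(rbind(MIR = mir, NBR = nbr))
  names(out) <- c("n_residues", "n_lysines", "n_ack")
  out$region <- rownames(out)
  class(out) <- c("RegionCounts", "data.frame")
  out
}

#' Region-wise acetylation frequencies and MIR/NBR enrichment ratios
#'
#' Per region, \code{pct_kac} is the acetyl-lysine count normalized by the
#' region's residue count (x100) and \code{pct_kac_per_k} by the region's
#' lysine count (x100, controlling for lysine abundance). Ratios divide the
#' MIR value by the NBR value and are flagged undefined when the NBR value
#' (or any required denominator) is zero; undefined ratios are excluded
#' from downstream averaging rather than imputed.
#'
#' @param counts \code{RegionCounts}.
#' @return list of class \code{EnrichmentStats}.
#' @export
frequency_stats <- function(counts) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  mir <- counts["MIR", ]; nbr <- counts["NBR", ]
  pk_mir <- pct(mir$n_ack, mir$n_residues)
  pk_nbr <- pct(nbr$n_ack, nbr$n_residues)
  pkk_mir <- pct(mir$n_ack, mir$n_lysines)
  pkk_nbr <- pct(nbr$n_ack, nbr$n_lysines)
  ratio <- function(m, n) {
    if (is.na(m) || is.na(n) || n == 0) list(value = NA_real_, undefined = TRUE)
    else list(value = m / n, undefined = FALSE)
  }
  r1 <- ratio(pk_mir, pk_nbr)
  r2 <- ratio(pkk_mir, pkk_nbr)
  structure(list(pct_kac_mir = pk_mir, pct_kac_nbr = pk_nbr,
                 pct_kac_per_k_mir = pkk_mir, pct_kac_per_k_nbr = pkk_nbr,
                 ratio_kac = r1$value, ratio_kac_undefined = r1$undefined,
                 ratio_kac_per_k = r2$value,
                 ratio_kac_per_k_undefined = r2$undefined),
            class = "EnrichmentStats")
}

#' Decimal rounding, halves away from zero
#'
#' Reproduces table-style printed precision: 2.05 rounds to 2.1 rather than
#' the IEEE/banker's 2.0 of \code{round()}. A small guard absorbs binary
#' representation error (e.g. \code{x * 100} landing at 464.7799...).
#'
#' @param x finite numeric vector.
#' @param ndigits decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, ndigits = 0) {
  p <- 10^ndigits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Classify a domain by where its acetylation falls
#'
#' Majority is decided on raw acetyl-lysine counts (MIR vs NBR);
#' exclusivity records whether all sites fall in one region. A domain with
#' no sites gets majority \code{tie} and exclusivity \code{none}.
#'
#' @param counts \code{RegionCounts}.
#' @return list of class \code{DomainClass}: \code{majority} in
#'   \code{MIR_majority}/\code{NBR_majority}/\code{tie}; \code{exclusivity}
#'   in \code{MIR_only}/\code{NBR_only}/\code{mixed}/\code{none}.
#' @export
classify_domain <- function(counts) {
  m <- counts["MIR", "n_ack"]; n <- counts["NBR", "n_ack"]
  majority <- if (m > n) "MIR_majority" else if (n > m) "NBR_majority" else "tie"
  exclusivity <- if (m == 0 && n == 0) "none"
    else if (n == 0) "MIR_only"
    else if (m == 0) "NBR_only"
    else "mixed"
  structure(list(majority = majority, exclusivity = exclusivity),
            class = "DomainClass")
}

#' Aggregate per-domain results into a family summary
#'
#' Counts are pooled (summed across domains before normalization), so the
#' pooled frequencies weight domains by their size rather than averaging
#' per-domain means. Majority/exclusivity fractions are computed over
#' domains with at least one site; ties are reported separately, and the
#' all-domain denominators are carried alongside.
#'
#' @param per_domain list, one element per domain, each with \code{counts}
#'   (\code{RegionCounts}) and \code{class} (\code{DomainClass}).
#' @param family family label.
#' @return list of class \code{FamilySummary}.
#' @export
aggregate_family <- function(per_domain, family = "") {
  if (length(per_domain) == 0L) stop("no domains to aggregate")
  pool <- Reduce(`+`, lapply(per_domain, function(d)
    as.matrix(d$counts[, c("n_residues", "n_lysines", "n_ack")])))
  pooled_counts <- region_counts(pool["MIR", ], pool["NBR", ])
  classes <- lapply(per_domain, `[[`, "class")
  has_sites <- vapply(per_domain, function(d)
    sum(d$counts$n_ack) > 0, logical(1))
  maj <- vapply(classes, `[[`, character(1), "majority")
  exc <- vapply(classes, `[[`, character(1), "exclusivity")
  n_with <- sum(has_sites)
  structure(list(
    family = family,
    n_domains = length(per_domain),
    n_with_sites = n_with,
    pooled_counts = pooled_counts,
    pooled_stats = frequency_stats(pooled_counts),
    fraction_mir_majority = if (n_with > 0)
      sum(maj == "MIR_majority" & has_sites) / n_with else NA_real_,
    fraction_mir_only = if (n_with > 0)
      sum(exc == "MIR_only") / n_with else NA_real_,
    fraction_mir_majority_all = mean(maj == "MIR_majority"),
    fraction_mir_only_all = mean(exc == "MIR_only"),
    n_ties = sum(maj == "tie" & has_sites)),
    class = "FamilySummary")
}

#' @export
print.FamilySummary <- function(x, ...) {
  st <- x$pooled_stats
  cat(sprintf(
    "FamilySummary %s: %d domains (%d with sites), %d ties\n", x$family,
    x$n_domains, x$n_with_sites, x$n_ties))
  cat(sprintf("  %%K_AC  MIR %.2f NBR %.2f ratio %s\n", st$pct_kac_mir,
              st$pct_kac_nbr,
              if (st$ratio_kac_undefined) "undef" else
                sprintf("%.2f", st$ratio_kac)))
  cat(sprintf("  %%K_AC/K MIR %.1f NBR %.1f ratio %s\n",
              st$pct_kac_per_k_mir, st$pct_kac_per_k_nbr,
              if (st$ratio_kac_per_k_undefined) "undef" else
                sprintf("%.2f", st$ratio_kac_per_k)))
  invisible(x)
}

# per-domain analysis of one (record, annotation) against a site table
analyze_domain <- function(record, ann, sites) {
  flags <- map_sites_to_domain(record, ann, sites)
  counts <- count_regions(record, ann, flags)
  list(record = record, annotation = ann, flags = flags, counts = counts,
       class = classify_domain(counts), stats = frequency_stats(counts))
}

#' Boundary-sensitivity sweep
#'
#' Repeats the full tally/classification per boundary perturbation delta:
#' every MIR definition is expanded or contracted via
#' \code{\link{adjust_boundaries}} and the family summaries recomputed. The
#' delta-0 row reproduces the base run exactly.
#'
#' @param domains list, one element per domain, each with \code{record},
#'   \code{annotation} and \code{family}.
#' @param sites \code{AcetylationSiteTable}.
#' @param deltas integer vector within \code{-2..+2}.
#' @return data.frame, one row per (delta, family) plus a pooled
#'   \code{Average} row per delta, with frequencies, ratios and
#'   classification fractions.
#' @export
sensitivity_sweep <- function(domains, sites, deltas = -2:2) {
  stopifnot(all(deltas %in% -2:2))
  out <- NULL
  for (d in deltas) {
    per <- lapply(domains, function(x)
      analyze_domain(x$record, adjust_boundaries(x$annotation, d), sites))
    fams <- vapply(domains, `[[`, character(1), "family")
    for (f in c(sort(unique(fams)), "Average")) {
      sel <- if (f == "Average") seq_along(per) else which(fams == f)
      fs <- aggregate_family(per[sel], f)
      out <- rbind(out, family_summary_row(fs, delta = d))
    }
  }
  out
}

family_summary_row <- function(fs, delta = NA_integer_) {
  st <- fs$pooled_stats
  data.frame(delta = delta, family = fs$family, n_domains = fs$n_domains,
             n_with_sites = fs$n_with_sites,
             mir_residues = fs$pooled_counts["MIR", "n_residues"],
             nbr_residues = fs$pooled_counts["NBR", "n_residues"],
             mir_lysines = fs$pooled_counts["MIR", "n_lysines"],
             nbr_lysines = fs$pooled_counts["NBR", "n_lysines"],
             mir_ack = fs$pooled_counts["MIR", "n_ack"],
             nbr_ack = fs$pooled_counts["NBR", "n_ack"],
             pct_kac_mir = st$pct_kac_mir, pct_kac_nbr = st$pct_kac_nbr,
             ratio_kac = st$ratio_kac,
             pct_kac_per_k_mir = st$pct_kac_per_k_mir,
             pct_kac_per_k_nbr = st$pct_kac_per_k_nbr,
             ratio_kac_per_k = st$ratio_kac_per_k,
             fraction_mir_majority = fs$fraction_mir_majority,
             fraction_mir_only = fs$fraction_mir_only,
             n_ties = fs$n_ties)
}

#' Permutation test of MIR acetylation enrichment
#'
#' Null model: the observed number of acetyl-lysines is reassigned
#' uniformly at random among the domain's lysines (without replacement);
#' the statistic is the MIR acetyl-lysine count. The one-sided p-value uses
#' add-one smoothing: \code{(1 + #(perm >= obs)) / (n_perm + 1)}. On a
#' two-region domain this null is hypergeometric, which serves as the exact
#' cross-check.
#'
#' @param counts \code{RegionCounts}.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list: \code{p_value}, \code{observed}, \code{n_perm}.
#' @export
permutation_enrichment_test <- function(counts, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 100)
  k_mir <- counts["MIR", "n_lysines"]; k_nbr <- counts["NBR", "n_lysines"]
  k_tot <- k_mir + k_nbr
  if (k_tot == 0L) stop("domain has no lysines")
  n_ack <- counts["MIR", "n_ack"] + counts["NBR", "n_ack"]
  obs <- counts["MIR", "n_ack"]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lys_is_mir <- c(rep(TRUE, k_mir), rep(FALSE, k_nbr))
  stat <- vapply(seq_len(n_perm), function(i)
    sum(lys_is_mir[sample.int(k_tot, n_ack)]), integer(1))
  list(p_value = (1 + sum(stat >= obs)) / (n_perm + 1),
       observed = obs, n_perm = n_perm)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Benjamini-Hochberg adjustment of many per-domain permutation p-values
#' @param p numeric vector of p-values.
#' @return adjusted p-values (\code{stats::p.adjust}, method "BH").
#' @export
adjust_permutation_pvalues <- function(p) stats::p.adjust(p, method = "BH")
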