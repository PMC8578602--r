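# Pairwise global alignment, identity/similarity scoring, Kabsch
# superposition, and the homology-clustering / template-assignment filters.

#' Alignment parameters
#'
#' Defaults follow EMBOSS NEEDLE protein defaults (BLOSUM62, gap open 10,
#' gap extend 0.5), the tool whose behaviour the sequence path emulates.
#' A gap run of length L costs \code{gap_open + gap_extend * L}.
#'
#' @param submat substitution matrix name (resolved from
#'   \pkg{Biostrings} data, e.g. \code{"BLOSUM62"}) or a numeric matrix with
#'   amino-acid letters as dimnames.
#' @param gap_open,gap_extend non-negative gap penalties.
#' @param identity_exclusion_pct members below this percent identity to the
#'   template cluster are excluded from the analysis (default 50).
#' @param c2_similarity_cutoff_pct C2 domains below this percent similarity
#'   to both C2A and C2B templates are flagged degenerate (default 50).
#' @param cluster_mode \code{"linkage"}: a member joins when it reaches the
#'   identity threshold against any current cluster member (single linkage);
#'   \code{"template"}: against the template only.
#' @param residual_cutoff Angstrom cutoff for dropping poorly superposed
#'   residue pairs during structural alignment refinement (default 5).
#' @param min_structure_pairs minimum surviving residue pairs for a
#'   structural alignment to be considered reliable (default 20).
#' @return list of class \code{AlignParams}.
#' @export
align_params <- function(submat = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, identity_exclusion_pct = 50,
                         c2_similarity_cutoff_pct = 50,
                         cluster_mode = c("linkage", "template"),
                         residual_cutoff = 5, min_structure_pairs = 20) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  cluster_mode <- match.arg(cluster_mode)
  if (is.character(submat)) submat <- get_submatrix(submat)
  structure(list(submat = submat, gap_open = gap_open,
                 gap_extend = gap_extend,
                 identity_exclusion_pct = identity_exclusion_pct,
                 c2_similarity_cutoff_pct = c2_similarity_cutoff_pct,
                 cluster_mode = cluster_mode,
                 residual_cutoff = residual_cutoff,
                 min_structure_pairs = min_structure_pairs),
            class = "AlignParams")
}

get_submatrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop("unknown substitution matrix: ", name)
  get(name, envir = e)
}

seq_to_idx <- function(s, alphabet) {
  ch <- strsplit(s, "")[[1]]
  idx <- match(ch, alphabet)
  if (anyNA(idx))
    stop("letter(s) not in substitution matrix: ",
         paste(unique(ch[is.na(idx)]), collapse = ""))
  idx
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under affine gap penalties: a gap run
#' of length L costs \code{gap_open + gap_extend * L}, and end gaps are
#' penalized. Traceback ties are broken deterministically
#' (aligned pair, then gap in \code{seqB}, then gap in \code{seqA}).
#'
#' @param seqA,seqB amino-acid strings (length >= 1).
#' @param params \code{\link{align_params}}.
#' @return object of class \code{AlignmentMap}: \code{pairs} (two-column
#'   matrix of aligned 1-based positions, strictly increasing in both
#'   coordinates), \code{score}, \code{identity_pct}, \code{similarity_pct},
#'   \code{aligned_cols} (total alignment columns), and the gapped column
#'   index vectors \code{col_a}, \code{col_b} (0 marks a gap).
#' @export
global_align <- function(seqA, seqB, params = align_params()) {
  if (nchar(seqA) == 0L || nchar(seqB) == 0L) stop("empty sequence")
  sm <- params$submat
  alphabet <- rownames(sm)
  res <- .nw_align_cpp(seq_to_idx(seqA, alphabet), seq_to_idx(seqB, alphabet),
                       sm, params$gap_open, params$gap_extend)
  map <- structure(list(
    pairs = cbind(posA = res$pair_a, posB = res$pair_b),
    score = res$score, col_a = res$col_a, col_b = res$col_b,
    aligned_cols = length(res$col_a), params = params),
    class = "AlignmentMap")
  ids <- identity_and_similarity(map, seqA, seqB)
  map$identity_pct <- ids[["identity_pct"]]
  map$similarity_pct <- ids[["similarity_pct"]]
  map
}

#' @export
print.AlignmentMap <- function(x, ...) {
  cat(sprintf(
    "AlignmentMap: %d pairs over %d columns, score %.1f, id %.1f%%, sim %.1f%%\n",
    nrow(x$pairs), x$aligned_cols, x$score,
    x$identity_pct, x$similarity_pct))
  invisible(x)
}

#' Percent identity and similarity of an alignment
#'
#' Identity is the fraction of matched columns over all alignment columns
#' excluding terminal overhangs (columns before the first and after the
#' last aligned pair); similarity counts aligned columns whose substitution
#' score is positive, over the same denominator, so internal gap columns
#' dilute both measures.
#'
#' @param map an \code{AlignmentMap} produced from \code{seqA}/\code{seqB}.
#' @param seqA,seqB the aligned sequences.
#' @return named numeric vector \code{identity_pct}, \code{similarity_pct}.
#' @export
identity_and_similarity <- function(map, seqA, seqB) {
  if (nrow(map$pairs) == 0L)
    return(c(identity_pct = 0, similarity_pct = 0))
  sm <- map$params$submat
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  # columns within the core (first..last aligned pair)
  paired_cols <- which(map$col_a > 0L & map$col_b > 0L)
  core <- seq(min(paired_cols), max(paired_cols))
  ncore <- length(core)
  ca <- map$col_a[core]; cb <- map$col_b[core]
  both <- ca > 0L & cb > 0L
  la <- a[ca[both]]; lb <- b[cb[both]]
  matches <- sum(la == lb)
  pos_score <- sum(sm[cbind(la, lb)] > 0)
  c(identity_pct = 100 * matches / ncore,
    similarity_pct = 100 * pos_score / ncore)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation mapping \code{coordsB} onto
#' \code{coordsA} with minimal RMSD; reflections are corrected so the
#' rotation determinant is +1.
#'
#' @param coordsA,coordsB n x 3 coordinate matrices (Angstrom).
#' @param correspondence two-column index matrix pairing rows of
#'   \code{coordsA} with rows of \code{coordsB}; defaults to row-by-row.
#' @return list of class \code{Superposition}: \code{rotation} (3 x 3,
#'   det +1), \code{translation} (length 3), \code{rmsd}, \code{n_pairs}.
#' @export
kabsch_superpose <- function(coordsA, coordsB,
                             correspondence = cbind(seq_len(nrow(coordsA)),
                                                    seq_len(nrow(coordsA)))) {
  A <- coordsA[correspondence[, 1], , drop = FALSE]
  B <- coordsB[correspondence[, 2], , drop = FALSE]
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 corresponding pairs")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cA - R %*% cB)
  Bfit <- t(R %*% t(B)) + matrix(tr, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((A - Bfit)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd, n_pairs = n),
            class = "Superposition")
}

apply_superposition <- function(sp, coords) {
  t(sp$rotation %*% t(coords)) +
    matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

domain_sequence <- function(record) {
  substr(record$sequence, record$domain_range[1], record$domain_range[2])
}

# one-letter sequence of the structure residues, read off the full-length
# sequence at the mapped positions
structure_letters <- function(record) {
  pos <- record$structure$pos
  keep <- !is.na(pos)
  list(letters = substring(record$sequence, pos[keep], pos[keep]),
       pos = pos[keep], xyz = record$structure$xyz[keep, , drop = FALSE])
}

#' Structural alignment of two domain records
#'
#' Seeds a residue correspondence by global alignment of the two
#' structure-derived sequences, superposes (Kabsch), drops pairs with a
#' residual Calpha distance above \code{params$residual_cutoff} (5 Angstrom
#' by default), and superposes once more on the survivors. The returned map
#' carries surviving pairs in full-length coordinates.
#'
#' @param template,target \code{DomainRecord}s carrying structures.
#' @param params \code{\link{align_params}}.
#' @return \code{AlignmentMap} with extra fields \code{rmsd} and
#'   \code{superposition}.
#' @export
structure_align <- function(template, target, params = align_params()) {
  if (is.null(template$structure) || is.null(target$structure))
    stop("both records must carry structures")
  st <- structure_letters(template)
  sq <- structure_letters(target)
  aln <- global_align(paste(st$letters, collapse = ""),
                      paste(sq$letters, collapse = ""), params)
  idx <- aln$pairs
  if (nrow(idx) < 3L) stop("too few aligned residues for superposition")
  sp <- kabsch_superpose(st$xyz, sq$xyz, idx)
  fit <- apply_superposition(sp, sq$xyz[idx[, 2], , drop = FALSE])
  resid <- sqrt(rowSums((st$xyz[idx[, 1], , drop = FALSE] - fit)^2))
  keep <- resid <= params$residual_cutoff
  if (sum(keep) < params$min_structure_pairs)
    stop("unreliable superposition: only ", sum(keep),
         " residue pairs within ", params$residual_cutoff, " Angstrom")
  idx <- idx[keep, , drop = FALSE]
  sp <- kabsch_superpose(st$xyz, sq$xyz, idx)
  out <- aln
  out$pairs <- cbind(posA = st$pos[idx[, 1]], posB = sq$pos[idx[, 2]])
  out$rmsd <- sp$rmsd
  out$superposition <- sp
  out
}

restrict_record_structure <- function(record, iv) {
  if (is.null(record$structure)) return(record)
  keep <- !is.na(record$structure$pos) &
    iv_contains(iv, record$structure$pos)
  record$structure <- list(xyz = record$structure$xyz[keep, , drop = FALSE],
                           pos = record$structure$pos[keep])
  record
}

#' Segment-wise alignment across a structural kink
#'
#' Some domains (e.g. kinked F-BARs) superpose poorly as a single rigid
#' body; each template segment is then aligned independently to the target
#' (structurally when both records carry structures, otherwise by sequence)
#' and the per-segment maps concatenated. Pairs of later segments that
#' would break strict monotonicity are dropped.
#'
#' @param template,target \code{DomainRecord}s.
#' @param segments interval matrix of template full-length segments
#'   (non-overlapping, ordered).
#' @param params \code{\link{align_params}}.
#' @return \code{AlignmentMap}; the per-segment RMSDs (structural path) are
#'   attached as \code{segment_rmsd}.
#' @export
segmented_align <- function(template, target, segments,
                            params = align_params()) {
  if (is.null(segments) || nrow(segments) == 0L)
    stop("empty segment list")
  iv_validate(segments, what = "segments")
  structural <- !is.null(template$structure) && !is.null(target$structure)
  pairs <- NULL
  seg_rmsd <- numeric()
  for (k in seq_len(nrow(segments))) {
    seg <- segments[k, ]
    if (structural) {
      sub_t <- restrict_record_structure(template,
                                         intervals(seg[1], seg[2]))
      m <- structure_align(sub_t, target, params)
      seg_rmsd <- c(seg_rmsd, m$rmsd)
      p <- m$pairs
    } else {
      seg_seq <- substr(template$sequence, seg[1], seg[2])
      m <- global_align(seg_seq, target$sequence, params)
      p <- m$pairs
      p[, 1] <- p[, 1] + seg[1] - 1L
    }
    pairs <- rbind(pairs, p)
  }
  # enforce strict monotonicity: keep earlier-segment pairs, drop later
  # conflicting ones
  keep <- logical(nrow(pairs))
  maxA <- 0L; maxB <- 0L
  for (r in seq_len(nrow(pairs))) {
    if (pairs[r, 1] > maxA && pairs[r, 2] > maxB) {
      keep[r] <- TRUE
      maxA <- pairs[r, 1]; maxB <- pairs[r, 2]
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  structure(list(pairs = pairs, score = NA_real_,
                 col_a = NULL, col_b = NULL,
                 aligned_cols = nrow(pairs), params = params,
                 identity_pct = NA_real_, similarity_pct = NA_real_,
                 segment_rmsd = seg_rmsd),
            class = "AlignmentMap")
}

#' Homology clustering with an identity-exclusion filter
#'
#' Grows a single-linkage cluster seeded at the family template: a member
#' joins when its percent identity (over domain subsequences) reaches the
#' exclusion threshold against any current cluster member
#' (\code{cluster_mode = "linkage"}) or against the template only
#' (\code{"template"}). Members below the threshold against every cluster
#' member are excluded from the analysis.
#'
#' @param records list of \code{DomainRecord}s of one family.
#' @param params \code{\link{align_params}}.
#' @param template_id protein_id of the template (default: first record).
#' @return list with \code{cluster} (character ids, template first),
#'   \code{excluded} (character ids), and \code{identity_to_template}.
#' @export
cluster_by_identity <- function(records, params = align_params(),
                                template_id = records[[1]]$protein_id) {
  ids <- vapply(records, `[[`, character(1), "protein_id")
  names(records) <- ids
  if (!template_id %in% ids) stop("template_id not among records")
  thr <- params$identity_exclusion_pct
  pair_identity <- function(r1, r2)
    global_align(domain_sequence(r1), domain_sequence(r2),
                 params)$identity_pct
  id_tpl <- vapply(records, function(r)
    if (r$protein_id == template_id) 100 else
      pair_identity(records[[template_id]], r), numeric(1))
  cluster <- template_id
  pending <- setdiff(ids, template_id)
  # cache of computed identities member -> cluster members
  repeat {
    added <- FALSE
    for (cand in pending) {
      hit <- if (params$cluster_mode == "template") {
        id_tpl[[cand]] >= thr
      } else {
        any(vapply(cluster, function(cm)
          (if (cm == template_id) id_tpl[[cand]] else
             pair_identity(records[[cm]], records[[cand]])) >= thr,
          logical(1)))
      }
      if (hit) {
        cluster <- c(cluster, cand)
        pending <- setdiff(pending, cand)
        added <- TRUE
      }
    }
    if (!added) break
  }
  list(cluster = cluster, excluded = pending,
       identity_to_template = id_tpl)
}

#' Assign a C2 domain to the C2A-like or C2B-like subtype
#'
#' The domain subsequence is globally aligned with both the C2A and the C2B
#' template; below the similarity cutoff against both it is flagged
#' degenerate (excluded from analysis), otherwise it is assigned to the
#' template with the higher percent similarity. Exact ties go to C2A-like
#' with a warning.
#'
#' @param record C2-family \code{DomainRecord}.
#' @param templateA,templateB the C2A and C2B template records.
#' @param params \code{\link{align_params}}.
#' @return list: \code{subtype} in \code{"C2A-like"}, \code{"C2B-like"},
#'   \code{"degenerate"}; \code{similarity_a}, \code{similarity_b}.
#' @export
assign_c2_subtype <- function(record, templateA, templateB,
                              params = align_params()) {
  if (!identical(record$family, "C2")) stop("record is not a C2 domain")
  simA <- global_align(domain_sequence(templateA), domain_sequence(record),
                       params)$similarity_pct
  simB <- global_align(domain_sequence(templateB), domain_sequence(record),
                       params)$similarity_pct
  cut <- params$c2_similarity_cutoff_pct
  subtype <- if (simA < cut && simB < cut) {
    "degenerate"
  } else if (simA == simB) {
    warning("exact similarity tie for '", record$protein_id,
            "'; assigning C2A-like")
    "C2A-like"
  } else if (simA > simB) "C2A-like" else "C2B-like"
  list(subtype = subtype, similarity_a = simA, similarity_b = simB)
}

#' Export an alignment as gapped pairwise FASTA
#' @param map \code{AlignmentMap} with column vectors.
#' @param seqA,seqB the aligned sequences.
#' @param ids two sequence identifiers.
#' @param path output FASTA.
#' @export
write_alignment_fasta <- function(map, seqA, seqB, ids, path) {
  if (is.null(map$col_a)) stop("map carries no gapped columns")
  a <- strsplit(seqA, "")[[1]]; b <- strsplit(seqB, "")[[1]]
  ga <- ifelse(map$col_a > 0L, a[pmax(map$col_a, 1L)], "-")
  gb <- ifelse(map$col_b > 0L, b[pmax(map$col_b, 1L)], "-")
  write_fasta(setNames(list(paste(ga, collapse = ""),
                            paste(gb, collapse = "")), ids), path)
}

#' Export aligned position pairs as TSV
#' @param map \code{AlignmentMap}.
#' @param path output TSV with columns \code{posA}, \code{posB} (1-based).
#' @export
write_alignment_tsv <- function(map, path) {
  write.table(as.data.frame(map$pairs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
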