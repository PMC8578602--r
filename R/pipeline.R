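# Orchestrates the full analysis from a single config: cluster/filter,
# align (structural when available, segment-wise across declared kinks),
# transfer region annotations, map sites, tally, classify, aggregate and
# sweep; every per-domain decision is recorded in a run manifest.

#' Validate a pipeline config
#'
#' Dry-runs the config checks: referenced paths exist, families reference
#' sequence ids present in the FASTA, deltas lie in the validated range.
#'
#' @param config list or path to a YAML config with keys \code{sequences},
#'   \code{sites}, \code{regions}, optional \code{structures_dir},
#'   \code{families} (each with \code{name}, \code{template},
#'   \code{members}), optional \code{c2} (\code{template_a},
#'   \code{template_b}), \code{structural_first}, \code{deltas},
#'   \code{seed}, \code{out_dir}. Relative paths resolve against the config
#'   file's directory.
#' @return the normalized config, invisibly; errors on any violation.
#' @export
validate_config <- function(config) {
  cfg <- load_config(config)
  for (key in c("sequences", "sites", "regions")) {
    if (is.null(cfg[[key]])) stop("config missing '", key, "'")
    if (!file.exists(cfg[[key]]))
      stop("config ", key, ": no such file: ", cfg[[key]])
  }
  if (!is.null(cfg$structures_dir) && !dir.exists(cfg$structures_dir))
    stop("config structures_dir: no such directory: ", cfg$structures_dir)
  if (!all(cfg$deltas %in% -2:2))
    stop("config deltas outside the validated range -2..+2")
  seqs <- read_fasta(cfg$sequences)
  regions <- read_region_config(cfg$regions)
  if (length(cfg$families) == 0L) stop("config declares no families")
  for (fam in cfg$families) {
    ids <- unique(c(fam$template, unlist(fam$members)))
    missing <- setdiff(ids, names(seqs))
    if (length(missing))
      stop("family ", fam$name, ": sequence id(s) not in FASTA: ",
           paste(missing, collapse = ", "))
    if (!fam$template %in% names(regions))
      stop("family ", fam$name, ": template '", fam$template,
           "' has no region definition")
  }
  invisible(cfg)
}

load_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    cfg <- yaml::read_yaml(config)
    for (key in c("sequences", "sites", "regions", "structures_dir")) {
      p <- cfg[[key]]
      if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p))
        cfg[[key]] <- file.path(base, p)
    }
  } else cfg <- config
  if (is.null(cfg$deltas)) cfg$deltas <- -2:2
  if (is.null(cfg$structural_first)) cfg$structural_first <- TRUE
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

load_record <- function(id, seqs, family, cfg) {
  str <- NULL
  if (!is.null(cfg$structures_dir)) {
    for (ext in c("pdb", "cif")) {
      f <- file.path(cfg$structures_dir, paste0(id, ".", ext))
      if (file.exists(f)) {
        raw <- read_structure(f, chain = "A")
        map <- map_structure_to_sequence(raw$sequence, seqs[[id]])
        str <- list(xyz = raw$xyz, pos = map)
        break
      }
    }
  }
  domain_record(id, seqs[[id]], family, structure = str)
}

template_annotation_from_config <- function(tdef) {
  mir <- tdef$mir
  if (!is.null(tdef$h0)) {
    # curated N-terminal helix treated as membrane-binding
    mir <- iv_merge_overlaps(rbind(mir, intervals(tdef$h0[1], tdef$h0[2])))
    dr <- c(min(tdef$domain_range[1], tdef$h0[1]), tdef$domain_range[2])
  } else dr <- tdef$domain_range
  region_annotation(dr, mir)
}

#' Run the full region-enrichment pipeline
#'
#' For each declared family: build domain records (attaching and mapping
#' structures when present), cluster members against the template and drop
#' those under the identity-exclusion threshold, assign C2 subtypes when C2
#' templates are declared (degenerate domains excluded), align each kept
#' member to its template (structural alignment preferred when both carry
#' structures; segment-wise across declared kink segments), transfer the
#' MIR/NBR annotation, map acetylation sites, tally, classify; then
#' aggregate per family and over all families, and run the
#' boundary-sensitivity sweep. Per-domain alignment failures are logged and
#' the run continues.
#'
#' @param config see \code{\link{validate_config}}.
#' @param out_dir output directory (overrides \code{config$out_dir}).
#' @return invisible list: \code{per_domain} (data.frame),
#'   \code{family_summary} (data.frame), \code{sensitivity} (data.frame),
#'   \code{exclusions}, \code{failures}, \code{manifest}. Written to
#'   \code{out_dir} as TSVs plus \code{manifest.json} when set.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  seqs <- read_fasta(cfg$sequences)
  sites <- read_sites(cfg$sites)
  regions <- read_region_config(cfg$regions)
  params <- do.call(align_params, if (is.null(cfg$align)) list()
                    else cfg$align)

  exclusions <- NULL; failures <- NULL
  analyzed <- list(); decisions <- list()

  for (fam in cfg$families) {
    fam_ids <- unique(c(fam$template, unlist(fam$members)))
    records <- lapply(fam_ids, function(id) {
      tryCatch(load_record(id, seqs, fam$name, cfg),
               error = function(e) e)
    })
    names(records) <- fam_ids
    bad <- vapply(records, inherits, logical(1), "condition")
    for (id in fam_ids[bad])
      failures <- rbind(failures, data.frame(
        protein_id = id, family = fam$name, stage = "load",
        reason = conditionMessage(records[[id]])))
    records <- records[!bad]
    if (length(records) == 0L) next

    tdef <- regions[[fam$template]]
    tpl_ann <- template_annotation_from_config(tdef)
    tpl <- records[[fam$template]]
    tpl$domain_range <- tpl_ann$domain_range

    cl <- cluster_by_identity(records, params, fam$template)
    for (id in cl$excluded)
      exclusions <- rbind(exclusions, data.frame(
        protein_id = id, family = fam$name, stage = "identity_filter",
        reason = sprintf("identity to template %.1f%% < %g%%",
                         cl$identity_to_template[[id]],
                         params$identity_exclusion_pct)))

    # C2 subtype assignment against declared C2A/C2B templates
    member_template <- setNames(rep(fam$template, length(cl$cluster)),
                                cl$cluster)
    subtype <- setNames(rep(NA_character_, length(cl$cluster)), cl$cluster)
    if (identical(fam$name, "C2") && !is.null(cfg$c2)) {
      ta <- records[[cfg$c2$template_a]]; tb <- records[[cfg$c2$template_b]]
      ta$domain_range <- regions[[cfg$c2$template_a]]$domain_range
      tb$domain_range <- regions[[cfg$c2$template_b]]$domain_range
      keep <- character()
      for (id in cl$cluster) {
        asg <- assign_c2_subtype(records[[id]], ta, tb, params)
        if (asg$subtype == "degenerate") {
          exclusions <- rbind(exclusions, data.frame(
            protein_id = id, family = fam$name, stage = "c2_filter",
            reason = sprintf("degenerate: similarity %.1f/%.1f%% below %g%%",
                             asg$similarity_a, asg$similarity_b,
                             params$c2_similarity_cutoff_pct)))
        } else {
          keep <- c(keep, id)
          subtype[id] <- asg$subtype
          member_template[id] <- if (asg$subtype == "C2A-like")
            cfg$c2$template_a else cfg$c2$template_b
        }
      }
      cl$cluster <- keep
    }

    for (id in cl$cluster) {
      res <- tryCatch({
        rec <- records[[id]]
        tpl_id <- member_template[[id]]
        this_tpl <- if (tpl_id == fam$template) tpl else {
          x <- records[[tpl_id]]
          x$domain_range <- regions[[tpl_id]]$domain_range
          x
        }
        this_ann <- if (tpl_id == fam$template) tpl_ann else
          template_annotation_from_config(regions[[tpl_id]])
        if (id == tpl_id) {
          ann <- this_ann
          path <- "template"
        } else {
          structural <- isTRUE(cfg$structural_first) &&
            !is.null(this_tpl$structure) && !is.null(rec$structure)
          if (structural && !is.null(tdef$kink_segments)) {
            map <- segmented_align(this_tpl, rec, tdef$kink_segments, params)
            path <- "structural_segmented"
          } else if (structural) {
            map <- structure_align(this_tpl, rec, params)
            path <- "structural"
          } else {
            map <- global_align(this_tpl$sequence, rec$sequence, params)
            path <- "sequence"
          }
          ann <- transfer_annotation(this_ann, rec, map)
        }
        rec$domain_range <- ann$domain_range
        a <- analyze_domain(rec, ann, sites)
        decisions[[id]] <- list(family = fam$name, path = path,
                                template = tpl_id,
                                subtype = subtype[[id]],
                                identity_to_template =
                                  unname(cl$identity_to_template[id]))
        a$family <- fam$name
        a$path <- path
        analyzed[[id]] <- a
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res))
        failures <- rbind(failures, data.frame(
          protein_id = id, family = fam$name, stage = "align_transfer",
          reason = res))
    }
  }

  if (length(analyzed) == 0L) stop("no domain could be analyzed")

  per_domain <- do.call(rbind, lapply(names(analyzed), function(id) {
    a <- analyzed[[id]]
    st <- a$stats
    data.frame(protein_id = id, family = a$family, path = a$path,
               domain_start = a$annotation$domain_range[1],
               domain_end = a$annotation$domain_range[2],
               mir_residues = a$counts["MIR", "n_residues"],
               nbr_residues = a$counts["NBR", "n_residues"],
               mir_lysines = a$counts["MIR", "n_lysines"],
               nbr_lysines = a$counts["NBR", "n_lysines"],
               mir_ack = a$counts["MIR", "n_ack"],
               nbr_ack = a$counts["NBR", "n_ack"],
               sites_outside_domain = length(a$flags$outside_pos),
               sites_quarantined = nrow(a$flags$quarantined),
               pct_kac_mir = st$pct_kac_mir, pct_kac_nbr = st$pct_kac_nbr,
               pct_kac_per_k_mir = st$pct_kac_per_k_mir,
               pct_kac_per_k_nbr = st$pct_kac_per_k_nbr,
               ratio_kac = st$ratio_kac,
               ratio_kac_per_k = st$ratio_kac_per_k,
               majority = a$class$majority,
               exclusivity = a$class$exclusivity)
  }))

  fams_of <- vapply(analyzed, `[[`, character(1), "family")
  family_summary <- do.call(rbind, lapply(
    c(sort(unique(fams_of)), "Average"), function(f) {
      sel <- if (f == "Average") seq_along(analyzed) else which(fams_of == f)
      family_summary_row(aggregate_family(analyzed[sel], f), delta = 0L)
    }))

  sweep_domains <- lapply(names(analyzed), function(id) list(
    record = analyzed[[id]]$record, annotation = analyzed[[id]]$annotation,
    family = analyzed[[id]]$family))
  sensitivity <- sensitivity_sweep(sweep_domains, sites, cfg$deltas)

  manifest <- list(
    config = cfg[setdiff(names(cfg), "families")],
    families = cfg$families,
    align_params = params[setdiff(names(params), "submat")],
    n_input_sites = attr(sites, "n_input_rows"),
    decisions = decisions,
    exclusions = exclusions, failures = failures,
    package_version = as.character(utils::packageVersion("mirenrich")),
    r_version = R.version.string)

  out <- list(per_domain = per_domain, family_summary = family_summary,
              sensitivity = sensitivity,
              exclusions = exclusions, failures = failures,
              analyzed = analyzed, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) write.table(df, file.path(out_dir, f),
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE)
    wt(per_domain, "per_domain.tsv")
    wt(family_summary, "family_summary.tsv")
    wt(sensitivity, "sensitivity.tsv")
    if (!is.null(exclusions)) wt(exclusions, "exclusions.tsv")
    if (!is.null(failures)) wt(failures, "failures.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(out)
}
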