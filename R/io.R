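# I/O for every external artifact the pipeline touches. All coordinates are
# normalized to 1-based positions on the full-length protein sequence;
# intervals are closed.

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# parent-residue mapping for common nonstandard residues; anything else -> X
NONSTANDARD_AA3 <- c(MSE = "M", SEC = "C", PYL = "K", SEP = "S", TPO = "T",
                     PTR = "Y", KCX = "K", ALY = "K", MLY = "K", CSO = "C",
                     CME = "C", HYP = "P")

#' Construct a domain record
#'
#' A domain record holds one family member: its full-length sequence, the
#' membrane-binding domain range on that sequence, its family (and optional
#' subtype), and optionally a Calpha trace with a per-residue mapping to
#' full-length positions.
#'
#' @param protein_id character identifier (matches the site table).
#' @param sequence full-length amino-acid sequence (upper-cased; canonical
#'   letters plus \code{X}).
#' @param family one of \code{"BAR"}, \code{"PX"}, \code{"C2"}, \code{"EHD"}.
#' @param domain_range closed interval \code{c(start, end)} in full-length
#'   1-based coordinates.
#' @param subtype optional subtype label (e.g. \code{"N-BAR"},
#'   \code{"C2A-like"}).
#' @param structure optional list with \code{xyz} (n x 3 matrix of Calpha
#'   coordinates, Angstrom) and \code{pos} (integer full-length positions,
#'   \code{NA} for unmapped residues).
#' @return object of class \code{DomainRecord}.
#' @export
domain_record <- function(protein_id, sequence, family,
                          domain_range = c(1L, nchar(sequence)),
                          subtype = NULL, structure = NULL) {
  sequence <- toupper(sequence)
  letters_ok <- strsplit(sequence, "")[[1]] %in% c(AA_CANONICAL, "X")
  if (!all(letters_ok))
    stop("sequence of '", protein_id, "' contains non-amino-acid letters: ",
         paste(unique(strsplit(sequence, "")[[1]][!letters_ok]), collapse = ""))
  domain_range <- as.integer(domain_range)
  if (!(domain_range[1] >= 1L && domain_range[1] <= domain_range[2] &&
        domain_range[2] <= nchar(sequence)))
    stop("domain_range of '", protein_id, "' outside sequence [1,",
         nchar(sequence), "]")
  if (!is.null(structure)) {
    stopifnot(is.matrix(structure$xyz), ncol(structure$xyz) == 3,
              length(structure$pos) == nrow(structure$xyz))
    mapped <- structure$pos[!is.na(structure$pos)]
    if (anyDuplicated(mapped))
      stop("structure of '", protein_id, "' maps two residues to one position")
  }
  structure(list(protein_id = protein_id, sequence = sequence,
                 family = family, subtype = subtype,
                 domain_range = domain_range, structure = structure),
            class = "DomainRecord")
}

#' @export
print.DomainRecord <- function(x, ...) {
  cat("DomainRecord", x$protein_id, sprintf("(%s%s)", x$family,
      if (!is.null(x$subtype)) paste0("/", x$subtype) else ""),
      "\n  length", nchar(x$sequence), " domain [",
      x$domain_range[1], ",", x$domain_range[2], "]",
      if (!is.null(x$structure))
        sprintf(" structure: %d Calpha", nrow(x$structure$xyz)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named list of upper-cased sequences (names are the full header
#'   lines up to the first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA parse error in ", path, ": no records")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0L))
    stop("FASTA parse error in ", path, ": empty record '",
         names(seqs)[nchar(seqs) == 0L][1], "'")
  as.list(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or list of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read Calpha coordinates from a PDB or mmCIF file
#'
#' Keeps one Calpha per residue in author numbering (altloc \code{' '} or
#' \code{'A'} only; duplicate altlocs collapse to the first kept record) and
#' derives a one-letter sequence from the 3-letter residue codes, mapping
#' common nonstandard residues (MSE etc.) to their parent letter and unknown
#' codes to \code{X}. Residues lacking a Calpha are skipped with a warning.
#'
#' @param path PDB (\code{.pdb}) or mmCIF (\code{.cif}) file.
#' @param chain chain identifier.
#' @return list with \code{sequence} (one-letter string), \code{xyz}
#'   (n x 3 matrix), \code{resno} (author residue numbers).
#' @export
read_structure <- function(path, chain) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$chain == chain & !is.na(at$chain), , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)
  n_res_all <- length(unique(paste(at$resno, at$insert)))
  at <- at[at$elety == "CA", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", " ", "A"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no Calpha atoms for chain '", chain, "' in ", path)
  key <- paste(at$resno, at$insert)
  at <- at[!duplicated(key), , drop = FALSE]
  if (nrow(at) < n_res_all)
    warning(n_res_all - nrow(at), " residue(s) without Calpha skipped in ",
            basename(path))
  res3 <- toupper(at$resid)
  one <- suppressWarnings(bio3d::aa321(res3))  # nonstandard handled below
  nonstd <- which(!(one %in% AA_CANONICAL))
  for (k in nonstd) {
    one[k] <- if (res3[k] %in% names(NONSTANDARD_AA3))
      NONSTANDARD_AA3[[res3[k]]] else "X"
  }
  list(sequence = paste(one, collapse = ""),
       xyz = unname(cbind(at$x, at$y, at$z)),
       resno = at$resno)
}

#' Read an acetylation-site table
#'
#' Expects a TSV with header columns \code{protein_id}, \code{position},
#' \code{residue}, \code{modification} (the layout of a PhosphoSitePlus-style
#' export). Duplicate (protein_id, position) rows are collapsed to the first
#' occurrence. An optional \code{min_evidence} numeric column is carried
#' through and can be used for filtering downstream; no filter is applied
#' here.
#'
#' @param path TSV file.
#' @return data.frame of class \code{AcetylationSiteTable}; attribute
#'   \code{n_input_rows} records the pre-deduplication row count.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_id", "position", "residue", "modification")
  if (!all(need %in% names(df)))
    stop("site table ", path, " missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  n_in <- nrow(df)
  if (n_in > 0L) {
    pos <- suppressWarnings(as.integer(df$position))
    bad <- is.na(pos) | pos < 1L | as.character(pos) != df$position
    if (any(bad))
      stop("non-integer or non-positive position in ", path, " row ",
           which(bad)[1], ": '", df$position[which(bad)[1]], "'")
    df$position <- pos
    df$residue <- toupper(df$residue)
    if (!all(df$residue %in% AA_CANONICAL))
      stop("unknown residue letter in ", path, ": '",
           df$residue[!(df$residue %in% AA_CANONICAL)][1], "'")
    df <- df[!duplicated(df[, c("protein_id", "position")]), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df$position <- integer()
  }
  structure(df, n_input_rows = n_in,
            class = c("AcetylationSiteTable", "data.frame"))
}

#' Write an acetylation-site table
#' @param sites data.frame with the site-table columns.
#' @param path output TSV.
#' @export
write_sites <- function(sites, path) {
  write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a template region-definition config
#'
#' YAML (or JSON) with a top-level \code{coords: 1-based-closed} key and a
#' \code{templates} map; each template carries \code{domain_range} and a
#' list of \code{mir} entries with an \code{interval} and optional
#' \code{note}, plus optional \code{h0} curated helix interval and optional
#' \code{kink_segments} for segment-wise alignment.
#'
#' @param path YAML/JSON file.
#' @return named list; per template: \code{domain_range}, \code{mir}
#'   (interval matrix), \code{notes}, \code{h0}, \code{kink_segments}.
#' @export
read_region_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$coords) || cfg$coords != "1-based-closed")
    stop("region config must declare coords: 1-based-closed")
  out <- lapply(cfg$templates, function(tp) {
    dr <- as.integer(unlist(tp$domain_range))
    mir_list <- tp$mir
    if (is.null(mir_list)) mir_list <- list()
    ivs <- do.call(rbind, lapply(mir_list, function(e)
      as.integer(unlist(e$interval))))
    iv <- if (is.null(ivs)) intervals() else intervals(ivs[, 1], ivs[, 2])
    iv_validate(iv, dr, "MIR")
    notes <- vapply(mir_list, function(e)
      if (is.null(e$note)) "" else as.character(e$note), character(1))
    ks <- NULL
    if (!is.null(tp$kink_segments)) {
      km <- do.call(rbind, lapply(tp$kink_segments, function(e)
        as.integer(unlist(e))))
      ks <- intervals(km[, 1], km[, 2])
    }
    h0 <- if (!is.null(tp$h0)) as.integer(unlist(tp$h0)) else NULL
    list(domain_range = dr, mir = iv, notes = notes, h0 = h0,
         kink_segments = ks)
  })
  out
}

#' Map structure-derived residues to full-length sequence positions
#'
#' PDB author numbering drifts from full-length numbering, so the
#' structure-derived sequence is globally aligned to the full-length
#' sequence; each structure residue gets the full-length position of its
#' aligned column, or \code{NA} when unaligned.
#'
#' @param struct_sequence one-letter sequence derived from the structure.
#' @param full_sequence full-length protein sequence.
#' @param min_identity minimum percent identity over aligned columns below
#'   which the pairing is rejected as a wrong chain/protein (default 90).
#' @return integer vector, one entry per structure residue (NA = unmapped).
#' @export
map_structure_to_sequence <- function(struct_sequence, full_sequence,
                                      min_identity = 90) {
  if (nchar(struct_sequence) == 0L || nchar(full_sequence) == 0L)
    stop("empty sequence")
  aln <- global_align(struct_sequence, full_sequence)
  sa <- strsplit(struct_sequence, "")[[1]]
  fa <- strsplit(full_sequence, "")[[1]]
  matched <- sum(sa[aln$pairs[, 1]] == fa[aln$pairs[, 2]])
  ident_aligned <- 100 * matched / max(1L, nrow(aln$pairs))
  if (ident_aligned < min_identity)
    stop(sprintf(
      "structure sequence matches full-length sequence at only %.1f%% identity",
      ident_aligned))
  map <- rep(NA_integer_, nchar(struct_sequence))
  map[aln$pairs[, 1]] <- aln$pairs[, 2]
  map
}
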