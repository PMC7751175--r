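# Alignment-based comparison of PEPC sequences across accession groups:
# pairwise substitution/indel counting, reference-coordinate mapping,
# ancestral/novel and fixed/polymorphic site classification, and
# third-codon-position extraction. Alignments are inputs (built with
# external tools); this module validates and compares, never aligns.

panel_groups <- c("non-C4", "weak-C4", "C4", "donor", "LGT", "reference")

#' Construct an aligned sequence panel
#'
#' @param sequences Named character vector of equal-length aligned
#'   sequences (gap character \code{-}); ids must be unique.
#' @param groups Named character vector or data.frame
#'   (\code{sequence_id}, \code{group}) assigning each sequence to one of
#'   \code{non-C4, weak-C4, C4, donor, LGT, reference}.
#' @param alphabet \code{"aa"}, \code{"nt"} or \code{"auto"} (guessed
#'   from residue composition).
#' @return Object of class \code{aligned_panel}: list with the residue
#'   \code{matrix} (rows = sequences), \code{groups}, \code{alphabet} and
#'   \code{length} (alignment columns).
#' @export
aligned_panel <- function(sequences, groups = NULL, alphabet = "auto") {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("sequences must have unique nonempty names")
  }
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("all aligned sequences must have equal length")
  }
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(mat) <- ids
  if (identical(alphabet, "auto")) {
    res <- mat[mat != "-"]
    nt_frac <- mean(res %in% c("A", "C", "G", "T", "U", "N"))
    alphabet <- if (length(res) && nt_frac > 0.9) "nt" else "aa"
  }
  valid <- if (alphabet == "nt") {
    c("A", "C", "G", "T", "U", "N", "-", "R", "Y", "S", "W", "K", "M",
      "B", "D", "H", "V")
  } else {
    c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X", "*", "-")
  }
  bad <- setdiff(unique(as.vector(mat)), valid)
  if (length(bad)) {
    stop("invalid ", alphabet, " character(s): ",
         paste(bad, collapse = ", "))
  }
  grp <- NULL
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      stopifnot(all(c("sequence_id", "group") %in% names(groups)))
      grp <- stats::setNames(as.character(groups$group),
                             as.character(groups$sequence_id))
    } else {
      grp <- groups
    }
    missing_ids <- setdiff(ids, names(grp))
    if (length(missing_ids)) {
      stop("no group assigned for: ", paste(missing_ids, collapse = ", "))
    }
    grp <- grp[ids]
    unknown <- setdiff(unique(grp), panel_groups)
    if (length(unknown)) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "),
           " (expected: ", paste(panel_groups, collapse = ", "), ")")
    }
  }
  structure(list(matrix = mat, groups = grp, alphabet = alphabet,
                 length = ncol(mat)),
            class = "aligned_panel")
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat("Aligned", if (x$alphabet == "aa") "protein" else "nucleotide",
      "panel:", nrow(x$matrix), "sequences x", x$length, "columns\n")
  if (!is.null(x$groups)) {
    print(table(x$groups))
  }
  invisible(x)
}

#' Read an aligned panel from FASTA and a group table
#'
#' @param fasta_path Aligned FASTA (protein or CDS).
#' @param groups Path to a delimited text file with columns
#'   \code{sequence_id} and \code{group}, or a data.frame, or NULL.
#' @param alphabet Passed to \code{\link{aligned_panel}}.
#' @return An \code{aligned_panel}.
#' @export
#' @examples
#' fa <- system.file("extdata", "synthetic_pepc_panel.fasta",
#'                   package = "c4pepc")
#' gr <- system.file("extdata", "synthetic_pepc_groups.tsv",
#'                   package = "c4pepc")
#' read_aligned_panel(fa, groups = gr)
read_aligned_panel <- function(fasta_path, groups = NULL,
                               alphabet = "auto") {
  ss <- tryCatch(Biostrings::readBStringSet(fasta_path),
                 error = function(e) stop("cannot read FASTA: ",
                                          conditionMessage(e)))
  seqs <- stats::setNames(as.character(ss), names(ss))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(groups) && length(groups) == 1L) {
    first <- readLines(groups, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
    groups <- utils::read.table(groups, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  }
  aligned_panel(seqs, groups = groups, alphabet = alphabet)
}

# residue = not a gap; ambiguity (X / N) and stops are still residues for
# gap bookkeeping but excluded from substitution and fixation counting
is_missing_char <- function(ch, alphabet) {
  if (alphabet == "nt") ch == "N" else ch %in% c("X", "*")
}

#' Count pairwise differences between two aligned sequences
#'
#' Substitutions are counted over columns where both sequences carry
#' unambiguous residues; columns gapped in both are ignored entirely, and
#' maximal gap runs private to one sequence count as single indel events
#' (a gap run in \code{b} is a deletion event, a gap run in \code{a} an
#' insertion event, so the two labels swap when the arguments swap).
#' Ambiguity characters (X for protein, N for nucleotide) are treated as
#' missing data.
#'
#' @param a,b Aligned sequences: equal-length character strings, or two
#'   ids when \code{panel} is given.
#' @param panel Optional \code{aligned_panel} from which \code{a} and
#'   \code{b} name rows.
#' @param alphabet Used when raw strings are given ("auto" to guess).
#' @return List of class \code{pairwise_diff}: \code{id_a}, \code{id_b},
#'   \code{substitutions}, \code{insertion_events},
#'   \code{deletion_events}, \code{compared_columns}.
#' @export
count_pairwise_differences <- function(a, b, panel = NULL,
                                       alphabet = "auto") {
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "aligned_panel"))
    if (!all(c(a, b) %in% rownames(panel$matrix))) {
      stop("sequence id not in panel")
    }
    va <- panel$matrix[a, ]; vb <- panel$matrix[b, ]
    id_a <- a; id_b <- b; alphabet <- panel$alphabet
  } else {
    if (nchar(a) != nchar(b)) stop("aligned lengths differ")
    tmp <- aligned_panel(c(a = a, b = b), alphabet = alphabet)
    va <- tmp$matrix["a", ]; vb <- tmp$matrix["b", ]
    id_a <- "a"; id_b <- "b"; alphabet <- tmp$alphabet
  }
  keep <- !(va == "-" & vb == "-")
  va <- va[keep]; vb <- vb[keep]
  gap_a <- va == "-"; gap_b <- vb == "-"
  both <- !gap_a & !gap_b
  informative <- both & !is_missing_char(va, alphabet) &
    !is_missing_char(vb, alphabet)
  n_runs <- function(x) {
    if (!length(x) || !any(x)) return(0L)
    r <- rle(x)
    sum(r$values)
  }
  structure(list(
    id_a = id_a, id_b = id_b,
    substitutions = sum(informative & va != vb),
    insertion_events = n_runs(gap_a),
    deletion_events = n_runs(gap_b),
    compared_columns = sum(informative)
  ), class = "pairwise_diff")
}

#' Pairwise substitution-count matrix for a panel
#'
#' @param panel An \code{aligned_panel} with >= 2 sequences.
#' @return Symmetric integer matrix of substitution counts with zero
#'   diagonal, dimnames = sequence ids.
#' @export
pairwise_matrix <- function(panel) {
  stopifnot(inherits(panel, "aligned_panel"))
  ids <- rownames(panel$matrix)
  if (length(ids) < 2L) stop("need >= 2 sequences")
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- count_pairwise_differences(ids[i], ids[j], panel = panel)
      m[i, j] <- m[j, i] <- d$substitutions
    }
  }
  m
}

#' Map alignment columns to ungapped reference coordinates
#'
#' Site numbering follows the ungapped reference sequence, 1-based.
#' Columns where the reference has a residue map to that residue's
#' position; columns gapped in the reference map to the preceding
#' position and are flagged as insertions (position 0 for insertions
#' before the first reference residue).
#'
#' @param panel An \code{aligned_panel}.
#' @param reference_id Row id of the reference sequence.
#' @return data.frame with \code{column}, \code{position},
#'   \code{is_insertion}.
#' @export
map_to_reference <- function(panel, reference_id) {
  stopifnot(inherits(panel, "aligned_panel"))
  if (!reference_id %in% rownames(panel$matrix)) {
    stop("reference sequence not in panel: ", reference_id)
  }
  ref <- panel$matrix[reference_id, ]
  if (all(ref == "-")) stop("reference sequence is all gaps")
  has_res <- ref != "-"
  pos <- cumsum(has_res)
  data.frame(column = seq_along(ref),
             position = pos,
             is_insertion = !has_res)
}

#' Flag pseudogene-like sequences
#'
#' A premature (internal) stop codon marks a sequence as pseudogene-like.
#' Protein panels are scanned for \code{*} before the last residue;
#' nucleotide panels are translated (ungapped, frame 1) and scanned the
#' same way.
#'
#' @param panel An \code{aligned_panel}.
#' @return Named logical vector, TRUE = pseudogene-like.
#' @export
flag_pseudogenes <- function(panel) {
  stopifnot(inherits(panel, "aligned_panel"))
  vapply(rownames(panel$matrix), function(id) {
    res <- panel$matrix[id, ]
    res <- res[res != "-"]
    if (panel$alphabet == "nt") {
      s <- paste(res[res != "N"], collapse = "")
      s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
      if (nchar(s) < 3L) return(FALSE)
      aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(s),
                              if.fuzzy.codon = "X")))
      res <- strsplit(aa, "")[[1L]]
    }
    any(res[-length(res)] == "*")
  }, logical(1))
}

#' Classify sites differing between focal non-C4 and C4 sequences
#'
#' For every alignment column where the two focal (cloned) sequences both
#' carry unambiguous residues that differ, records the reference-numbered
#' position and classifies the C4 residue as \emph{ancestral} (observed
#' among the non-C4 ortholog group) or \emph{novel}, and as \emph{fixed}
#' (shared by every C4-group sequence with a residue at the column) or
#' \emph{polymorphic}. Pseudogene-like sequences (internal stop codons)
#' are excluded from the fixation assessment by default.
#'
#' @param panel An \code{aligned_panel} with group labels.
#' @param focal_nonC4_id,focal_C4_id Row ids of the cloned non-C4 and C4
#'   sequences.
#' @param reference_id Row id providing the site numbering.
#' @param ancestral_rule \code{"membership"} (C4 residue present in >= 1
#'   non-C4 ortholog) or \code{"majority"} (C4 residue is the modal
#'   non-C4 state).
#' @param include_pseudogenes Include pseudogene-like C4 sequences in the
#'   fixation assessment.
#' @return data.frame with one row per classified site:
#'   \code{reference_position}, \code{column}, \code{nonC4_residue},
#'   \code{c4_residue}, \code{c4_state} (ancestral/novel),
#'   \code{fixation} (fixed/polymorphic), and residue spectra per group
#'   (e.g. \code{"A:3;S:1"}) in \code{non_c4_spectrum},
#'   \code{weak_c4_spectrum}, \code{c4_spectrum}.
#' @export
classify_sites <- function(panel, focal_nonC4_id, focal_C4_id,
                           reference_id,
                           ancestral_rule = c("membership", "majority"),
                           include_pseudogenes = FALSE) {
  stopifnot(inherits(panel, "aligned_panel"))
  ancestral_rule <- match.arg(ancestral_rule)
  if (is.null(panel$groups)) stop("panel has no group labels")
  ids <- rownames(panel$matrix)
  for (id in c(focal_nonC4_id, focal_C4_id, reference_id)) {
    if (!id %in% ids) stop("sequence not in panel: ", id)
  }
  refmap <- map_to_reference(panel, reference_id)
  pseudo <- flag_pseudogenes(panel)

  non_c4_ids <- ids[panel$groups == "non-C4"]
  weak_ids <- ids[panel$groups == "weak-C4"]
  c4_ids <- ids[panel$groups == "C4"]
  if (!include_pseudogenes) {
    c4_fix_ids <- c4_ids[!pseudo[c4_ids]]
  } else {
    c4_fix_ids <- c4_ids
  }

  a <- panel$matrix[focal_nonC4_id, ]
  b <- panel$matrix[focal_C4_id, ]
  miss <- function(ch) ch == "-" | is_missing_char(ch, panel$alphabet)
  candidate <- !miss(a) & !miss(b) & a != b

  spectrum <- function(col, group_ids) {
    res <- panel$matrix[group_ids, col]
    res <- res[!miss(res)]
    if (!length(res)) return("")
    tab <- sort(table(res), decreasing = TRUE)
    paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ";")
  }

  rows <- lapply(which(candidate), function(col) {
    nc4_states <- panel$matrix[non_c4_ids, col]
    nc4_states <- nc4_states[!miss(nc4_states)]
    c4_res <- b[col]
    ancestral <- if (ancestral_rule == "membership") {
      c4_res %in% nc4_states
    } else {
      length(nc4_states) > 0 &&
        c4_res == names(sort(table(nc4_states), decreasing = TRUE))[1L]
    }
    fix_states <- panel$matrix[c4_fix_ids, col]
    fix_states <- fix_states[!miss(fix_states)]
    fixed <- length(fix_states) > 0 && all(fix_states == c4_res)
    data.frame(
      reference_position = refmap$position[col],
      column = col,
      nonC4_residue = a[col],
      c4_residue = c4_res,
      c4_state = if (ancestral) "ancestral" else "novel",
      fixation = if (fixed) "fixed" else "polymorphic",
      non_c4_spectrum = spectrum(col, non_c4_ids),
      weak_c4_spectrum = if (length(weak_ids)) spectrum(col, weak_ids)
                         else "",
      c4_spectrum = if (length(c4_ids)) spectrum(col, c4_ids) else "",
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(reference_position = integer(0), column = integer(0),
                      nonC4_residue = character(0),
                      c4_residue = character(0), c4_state = character(0),
                      fixation = character(0),
                      non_c4_spectrum = character(0),
                      weak_c4_spectrum = character(0),
                      c4_spectrum = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract third codon positions from a CDS alignment
#'
#' Returns alignment columns 3, 6, 9, ... (reading frame starting at
#' column 1), as used for phylogenetic inference that avoids biases from
#' convergent protein-level adaptation. A trailing remainder (length not
#' divisible by 3) is truncated with a warning, and sequences whose
#' private gap runs are not multiples of 3 (frame shifts) are listed in a
#' warning.
#'
#' @param x Named character vector of aligned CDS, or an
#'   \code{aligned_panel}.
#' @return Same type as the input, reduced to third-codon columns
#'   (length = floor(L/3)).
#' @export
extract_third_codon_positions <- function(x) {
  is_panel <- inherits(x, "aligned_panel")
  mat <- if (is_panel) x$matrix
         else do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  L <- ncol(mat)
  if (L == 0L) return(if (is_panel) x else stats::setNames(
    character(length(x)), names(x)))
  if (L %% 3L != 0L) {
    warning("alignment length ", L, " not divisible by 3; trailing ",
            L %% 3L, " column(s) truncated")
  }
  shifted <- apply(mat, 1L, function(row) {
    r <- rle(row == "-")
    any(r$lengths[r$values] %% 3L != 0L)
  })
  if (any(shifted)) {
    warning("gap run length not a multiple of 3 (possible frame shift) ",
            "in: ", paste(rownames(mat)[shifted], collapse = ", "))
  }
  cols <- seq(3L, 3L * (L %/% 3L), by = 3L)
  red <- mat[, cols, drop = FALSE]
  seqs <- stats::setNames(apply(red, 1L, paste, collapse = ""),
                          rownames(mat))
  if (is_panel) {
    aligned_panel(seqs, groups = x$groups, alphabet = x$alphabet)
  } else {
    seqs
  }
}

#' Overlap of classified sites with a user-supplied site list
#'
#' Intersects the reference positions of a site classification with an
#' externally provided list (for instance previously reported convergent
#' C4 sites).
#'
#' @param classified Output of \code{\link{classify_sites}}.
#' @param site_list Integer vector of reference positions.
#' @return List with \code{count} and sorted \code{positions} of the
#'   overlap.
#' @export
overlap_with_site_list <- function(classified, site_list) {
  pos <- intersect(classified$reference_position, site_list)
  list(count = length(pos), positions = sort(pos))
}
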