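#' Simulate a toy aligned panel with planted site classes
#'
#' Builds a small protein alignment around a focal non-C4 / C4 pair with
#' known ground truth: a configurable number of sites where the C4
#' residue is ancestral (also present in a non-C4 ortholog), novel and
#' fixed among the C4 group, or novel and polymorphic; optionally one
#' in-frame deletion private to a C4 sequence. The reference sequence is
#' gapless, so reference positions equal alignment columns.
#'
#' @param seed Integer seed.
#' @param length Alignment columns.
#' @param n_non_c4,n_weak,n_c4 Group sizes (the focal sequences count
#'   toward their groups).
#' @param n_ancestral,n_novel_fixed,n_novel_poly Planted site counts.
#' @param with_indel Plant a 3-column deletion in one non-focal C4
#'   sequence.
#' @return List with \code{panel} (an \code{\link{aligned_panel}}),
#'   \code{focal_nonC4}, \code{focal_C4}, \code{reference}, and
#'   \code{truth}: the planted positions per class.
#' @export
simulate_toy_panel <- function(seed = 1L, length = 60L,
                               n_non_c4 = 4L, n_weak = 2L, n_c4 = 5L,
                               n_ancestral = 4L, n_novel_fixed = 1L,
                               n_novel_poly = 3L, with_indel = TRUE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  n_sites <- n_ancestral + n_novel_fixed + n_novel_poly
  stopifnot(length >= n_sites + 6L, n_non_c4 >= 2L, n_c4 >= 2L)
  with_seed(seed, {
    base <- sample(aa, length, replace = TRUE)
    sites <- sort(sample(seq_len(length), n_sites))
    cls <- rep(c("ancestral", "novel_fixed", "novel_poly"),
               c(n_ancestral, n_novel_fixed, n_novel_poly))
    cls <- sample(cls)  # interleave classes along the alignment
    c4_res <- vapply(sites, function(s) sample(setdiff(aa, base[s]), 1L),
                     character(1))

    c4_seq <- base
    c4_seq[sites] <- c4_res

    mk <- function(x) paste(x, collapse = "")
    seqs <- list(); groups <- character(0)
    add <- function(id, vec, group) {
      seqs[[id]] <<- mk(vec); groups[id] <<- group
    }
    add("REF", base, "reference")
    add("focal_nonC4", base, "non-C4")
    # non-C4 orthologs: copies of base; the first carries the C4 residue
    # at every planted ancestral site
    for (i in seq_len(n_non_c4 - 1L)) {
      v <- base
      if (i == 1L) {
        anc <- sites[cls == "ancestral"]
        v[anc] <- c4_res[cls == "ancestral"]
      }
      add(sprintf("nonC4_%d", i), v, "non-C4")
    }
    for (i in seq_len(n_weak)) {
      add(sprintf("weak_%d", i), base, "weak-C4")
    }
    add("focal_C4", c4_seq, "C4")
    poly <- sites[cls == "novel_poly"]
    for (i in seq_len(n_c4 - 1L)) {
      v <- c4_seq
      # each polymorphic site reverts to the base residue in one C4 member
      if (length(poly)) {
        back <- poly[(seq_along(poly) - 1L) %% (n_c4 - 1L) + 1L == i]
        v[back] <- base[back]
      }
      if (with_indel && i == 1L) {
        free <- setdiff(seq_len(length - 2L),
                        unlist(lapply(sites, function(s) (s - 2L):s)))
        start <- free[1L]
        v[start:(start + 2L)] <- "-"
      }
      add(sprintf("C4_%d", i), v, "C4")
    }
    panel <- aligned_panel(unlist(seqs), groups = groups)
    list(panel = panel,
         focal_nonC4 = "focal_nonC4", focal_C4 = "focal_C4",
         reference = "REF",
         truth = list(ancestral = sites[cls == "ancestral"],
                      novel_fixed = sites[cls == "novel_fixed"],
                      novel_poly = sites[cls == "novel_poly"]))
  })
}
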