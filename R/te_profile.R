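#' Transposable-element landscape statistics
#'
#' Per-genome TE landscape summaries from a copy-to-family table and
#' all-vs-all self-alignment hits: copy and family counts, the family
#' saturation percentages P_25f and P_75f (share of the most copy-rich
#' families accounting for 25% / 75% of copies), the within-genome identity
#' profile of the TE complement, and shared-family presence matrices across
#' species.
#'
#' @name te-profile
NULL

#' Filter pairwise TE alignment hits
#'
#' Keeps hits with identity >= \code{min_identity} and alignment length >=
#' \code{min_length} (both boundaries inclusive) and drops query==subject
#' self-hits. Reciprocal duplicates are kept unless \code{dedupe}.
#'
#' @param hits data.frame with qseqid, sseqid, pident, length columns
#' @param min_identity minimum percent identity (default 70)
#' @param min_length minimum alignment length in bp (default 80)
#' @param dedupe drop reciprocal duplicates (unordered pair kept once)
#' @return the filtered hits
#' @export
filter_hits <- function(hits, min_identity = 70, min_length = 80,
                        dedupe = FALSE) {
  h <- hits[hits$pident >= min_identity & hits$length >= min_length &
            hits$qseqid != hits$sseqid, , drop = FALSE]
  if (dedupe) {
    key <- paste(pmin(h$qseqid, h$sseqid), pmax(h$qseqid, h$sseqid))
    h <- h[!duplicated(key), , drop = FALSE]
  }
  rownames(h) <- NULL
  h
}

#' Family saturation percentage
#'
#' Sorts families by copy count descending (ties by family name), finds
#' the smallest k whose cumulative copies reach fraction q of all copies,
#' and returns 100 k / (number of families).
#'
#' @param copies data.frame(copy_id, family_id, ...)
#' @param q target fraction in (0, 1)
#' @return percentage of families
#' @export
family_saturation <- function(copies, q) {
  stopifnot(q > 0, q < 1)
  if (!nrow(copies)) stop("empty copy table")
  cnt <- table(copies$family_id)
  ord <- order(-as.vector(cnt), names(cnt))
  cum <- cumsum(as.vector(cnt)[ord])
  k <- which(cum >= q * sum(cnt))[1]
  100 * k / length(cnt)
}

#' Identity profile of the TE complement
#'
#' Bins filtered hit identities (default 1% bins over [70, 100]) and
#' returns counts plus a normalized density.
#'
#' @param hits filtered hits (\code{\link{filter_hits}})
#' @param breaks bin breaks (default \code{seq(70, 100, by = 1)})
#' @return data.frame(bin_low, bin_high, count, density); empty hits give
#'   an empty histogram with a warning
#' @export
identity_profile <- function(hits, breaks = seq(70, 100, by = 1)) {
  if (!nrow(hits)) {
    warning("no hits: empty identity profile")
    return(data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      count = integer(0), density = numeric(0)))
  }
  h <- graphics::hist(pmin(hits$pident, max(breaks)), breaks = breaks,
                      plot = FALSE, include.lowest = TRUE, right = FALSE)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             count = h$counts, density = h$density)
}

#' Full TE profile of one genome
#'
#' @param copies copy-to-family table for one species
#' @param hits raw pairwise hits (filtered internally)
#' @param species species label
#' @param min_identity,min_length hit filters
#' @return list(species, N_c = total copies, N_f = families, P_25f, P_75f,
#'   histogram)
#' @export
te_profile <- function(copies, hits, species = NA_character_,
                       min_identity = 70, min_length = 80) {
  fh <- filter_hits(hits, min_identity, min_length)
  list(species = species, N_c = nrow(copies),
       N_f = length(unique(copies$family_id)),
       P_25f = family_saturation(copies, 0.25),
       P_75f = family_saturation(copies, 0.75),
       histogram = identity_profile(fh))
}

#' Shared TE family presence matrix across species
#'
#' @param family_lists named list species -> character vector of families
#' @return list(matrix = families x species 0/1 matrix, species_counts =
#'   per-family number of species, clustering = Ward/Euclidean
#'   \code{hclust} of species columns, or NULL for < 3 species)
#' @export
shared_family_matrix <- function(family_lists) {
  stopifnot(length(family_lists) >= 2)
  fams <- sort(unique(unlist(family_lists)))
  sp <- names(family_lists)
  m <- vapply(sp, function(s) as.integer(fams %in% family_lists[[s]]),
              integer(length(fams)))
  m <- matrix(m, nrow = length(fams), dimnames = list(fams, sp))
  cl <- if (length(sp) >= 3)
    stats::hclust(stats::dist(t(m), method = "euclidean"), method = "ward.D2")
  else NULL
  list(matrix = m, species_counts = rowSums(m), clustering = cl)
}
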