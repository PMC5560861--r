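#' Standard-format input/output
#'
#' Readers and writers for the formats every stage touches: GFF3 gene
#' models (via rtracklayer), OrthoFinder-style orthogroup TSVs, Newick
#' trees (via ape), pfam_scan-style domain tables, tabular BLAST hits and
#' BED intervals. GFF3 coordinates are 1-based inclusive; BED is 0-based
#' half-open; all internal interval arithmetic is done in 0-based half-open
#' with conversion at the boundary.
#'
#' @name io-formats
NULL

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features into one gene model per mRNA. When a gene
#' has several mRNAs, the isoform with the longest total CDS is kept.
#' Introns are the gaps between consecutive CDS segments in transcription
#' order (on the minus strand, transcription order reverses genomic order).
#'
#' @param gff3_path path to a GFF3 file
#' @param species species label to attach to every gene model
#' @return object of class \code{gene_models}: a data.frame with one row per
#'   kept mRNA and columns gene_id, species, scaffold, strand,
#'   protein_length (aa, NA if CDS length not divisible by 3), n_introns,
#'   cds_len, partial (logical), plus a list column \code{cds_segments} of
#'   2-column start/end matrices (1-based inclusive, sorted 5' to 3' in
#'   transcription order)
#' @export
read_gene_models <- function(gff3_path, species = NA_character_) {
  g <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(g)
  cds <- df[tolower(df$type) == "cds", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features in ", gff3_path)
  parent <- vapply(cds$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  skipped <- sum(is.na(parent))
  if (skipped) warning(skipped, " CDS features without parent linkage skipped")
  cds <- cds[!is.na(parent), , drop = FALSE]
  parent <- parent[!is.na(parent)]
  # mRNA -> gene map (fall back to the mRNA id itself)
  mrna <- df[tolower(df$type) %in% c("mrna", "transcript"), , drop = FALSE]
  gene_of <- stats::setNames(
    vapply(mrna$Parent, function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1)),
    mrna$ID)
  rows <- lapply(split(seq_len(nrow(cds)), parent), function(i) {
    seg <- cbind(start = cds$start[i], end = cds$end[i])
    seg <- seg[order(seg[, "start"]), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg[-1, "start"] <= seg[-nrow(seg), "end"])) {
      warning("overlapping CDS segments in mRNA ", parent[i[1]], "; record rejected")
      return(NULL)
    }
    strand <- as.character(cds$strand[i[1]])
    if (strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    len <- sum(seg[, "end"] - seg[, "start"] + 1)
    mid <- parent[i[1]]
    gid <- gene_of[mid]
    if (is.na(gid)) gid <- mid
    data.frame(gene_id = unname(gid), mrna_id = mid,
               species = species, scaffold = as.character(cds$seqnames[i[1]]),
               strand = strand, cds_len = len,
               protein_length = if (len %% 3 == 0) len %/% 3 else NA_integer_,
               partial = len %% 3 != 0, n_introns = nrow(seg) - 1L,
               cds_segments = I(list(seg)))
  })
  out <- do.call(rbind, rows)
  # longest-CDS isoform per gene
  out <- out[order(out$gene_id, -out$cds_len), , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models as GFF3
#'
#' @param gm a \code{gene_models} data.frame
#' @param path output path
#' @export
write_gene_models <- function(gm, path) {
  lines <- c("##gff-version 3")
  for (r in seq_len(nrow(gm))) {
    seg <- gm$cds_segments[[r]]
    gstart <- min(seg[, "start"]); gend <- max(seg[, "end"])
    at <- function(id, par = NULL)
      paste0("ID=", id, if (!is.null(par)) paste0(";Parent=", par))
    mk <- function(type, s, e, attr)
      paste(gm$scaffold[r], "archevol", type, s, e, ".", gm$strand[r], ".",
            attr, sep = "\t")
    gid <- gm$gene_id[r]; mid <- paste0(gid, ".t1")
    lines <- c(lines, mk("gene", gstart, gend, at(gid)),
               mk("mRNA", gstart, gend, at(mid, gid)),
               vapply(seq_len(nrow(seg)), function(k)
                 mk("CDS", seg[k, "start"], seg[k, "end"],
                    paste0("ID=", mid, ".cds;Parent=", mid)), character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Intron coordinates and phases of one gene model
#'
#' Introns are the gaps between consecutive CDS segments in transcription
#' order; the phase of an intron is (number of coding nucleotides 5' of the
#' intron) mod 3.
#'
#' @param gm_row one row of a \code{gene_models} data.frame
#' @return data.frame(start, end, phase, coding_nt_before); genomic 1-based
#'   inclusive intron spans, ordered 5' to 3'
#' @export
gene_introns <- function(gm_row) {
  seg <- gm_row$cds_segments[[1]]
  n <- nrow(seg)
  if (n < 2)
    return(data.frame(start = integer(0), end = integer(0),
                      phase = integer(0), coding_nt_before = integer(0)))
  lens <- seg[, "end"] - seg[, "start"] + 1
  before <- cumsum(lens)[-n]
  if (gm_row$strand == "+") {
    ist <- seg[-n, "end"] + 1L; ien <- seg[-1, "start"] - 1L
  } else {
    ist <- seg[-1, "end"] + 1L; ien <- seg[-n, "start"] - 1L
  }
  data.frame(start = as.integer(ist), end = as.integer(ien),
             phase = as.integer(before %% 3),
             coding_nt_before = as.integer(before))
}

#' Read an orthogroup table
#'
#' OrthoFinder-style TSV: first column orthogroup id, one column per
#' species; cells are comma-separated gene ids, blank for absence.
#'
#' @param tsv_path path to the TSV
#' @return an \code{ortholog_table}: named list orthogroup ->
#'   (named list species -> character vector of gene ids)
#' @export
read_orthogroups <- function(tsv_path) {
  tab <- utils::read.delim(tsv_path, check.names = FALSE,
                           colClasses = "character")
  sp <- colnames(tab)[-1]
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- lapply(sp, function(s) {
      cell <- trimws(tab[i, s])
      if (!nzchar(cell)) character(0)
      else trimws(strsplit(cell, ",")[[1]])
    })
    names(row) <- sp
    row
  })
  names(out) <- tab[[1]]
  all_genes <- unlist(out, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup))
    stop("gene id(s) present in more than one orthogroup: ",
         paste(utils::head(dup, 5), collapse = ", "))
  structure(out, class = "ortholog_table")
}

#' Write an orthogroup table
#' @param og an \code{ortholog_table}
#' @param path output TSV path
#' @export
write_orthogroups <- function(og, path) {
  sp <- names(og[[1]])
  rows <- vapply(names(og), function(id)
    paste(c(id, vapply(sp, function(s) paste(og[[id]][[s]], collapse = ","),
                       character(1))), collapse = "\t"), character(1))
  writeLines(c(paste(c("Orthogroup", sp), collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a rooted species or gene tree
#'
#' @param newick_path path to a Newick file
#' @return an \code{ape} \code{phylo}, rooted, with unique leaf names;
#'   missing branch lengths default to 1 with a warning; a single-leaf tree
#'   is accepted with a warning
#' @export
read_tree <- function(newick_path) {
  txt <- paste(readLines(newick_path, warn = FALSE), collapse = "")
  if (grepl("^\\([^(),]+\\);?$", trimws(txt))) {
    warning("degenerate single-leaf tree")
    lab <- sub(":.*", "", gsub("[();]", "", trimws(txt)))
    tr <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = lab, Nnode = 1L,
               edge.length = 1, node.label = "N1")
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("unreadable tree in ", newick_path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 1")
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  label_tree_nodes(tr)
}

#' Read a pfam_scan-style domain table
#'
#' @param tsv_path TSV with columns protein_id, domain_id, ali_start,
#'   ali_end, species
#' @return data.frame with those columns
#' @export
read_domain_table <- function(tsv_path) {
  d <- utils::read.delim(tsv_path, check.names = FALSE)
  need <- c("protein_id", "domain_id", "ali_start", "ali_end", "species")
  if (!all(need %in% colnames(d)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read tabular BLAST hits (outfmt 6 dialect)
#'
#' @param path TSV with the 12 standard columns (no header)
#' @return data.frame with qseqid, sseqid, pident, length, mismatch,
#'   gapopen, qstart, qend, sstart, send, evalue, bitscore
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  d <- utils::read.delim(path, header = FALSE)
  if (ncol(d) < 12) stop("expected 12 tab-separated columns")
  d <- d[, 1:12]
  colnames(d) <- cols
  bad <- !is.finite(suppressWarnings(as.numeric(d$pident)))
  if (any(bad)) {
    warning(sum(bad), " malformed hit rows skipped")
    d <- d[!bad, , drop = FALSE]
  }
  d$pident <- as.numeric(d$pident)
  d
}

#' Read BED intervals
#'
#' BED is 0-based half-open; returned intervals are converted to the
#' internal 0-based half-open convention unchanged.
#'
#' @param path BED3+ file
#' @return data.frame(chrom, start, end) with 0-based half-open coordinates
#' @export
read_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE)
  colnames(d)[1:3] <- c("chrom", "start", "end")
  d[, 1:3]
}
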