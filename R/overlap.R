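#' Intersect QTL intervals with IBD segments
#'
#' A QTL counts as "in IBD" when at least one base pair overlaps any IBD
#' segment of the pedigree's pairs.  Each overlapping (QTL, segment)
#' combination yields one record with the intersection interval and the
#' contributing pair.  Per-trait tallies (x of y QTL in IBD) are
#' reported alongside.
#'
#' @param qtls feature data.frame (kind "QTL") from [read_features()].
#' @param segments IBD segment table.
#' @param pedigree_label optional label attached to every record.
#' @return list with `overlaps` (data.frame `qtl_id`, `trait`, `chrom`,
#'   `ov_start`, `ov_end`, `pair`, `sample_a`, `sample_b`,
#'   `pedigree_label`) and `trait_tally` (`trait`, `n_qtl`,
#'   `n_qtl_in_ibd`).
#' @export
intersect_qtl_ibd <- function(qtls, segments, pedigree_label = NA_character_) {
  empty <- data.frame(qtl_id = character(0), trait = character(0),
                      chrom = character(0), ov_start = integer(0),
                      ov_end = integer(0), pair = character(0),
                      sample_a = character(0), sample_b = character(0),
                      pedigree_label = character(0))
  tally_all <- function(hit_ids) {
    if (nrow(qtls) == 0) {
      return(data.frame(trait = character(0), n_qtl = integer(0),
                        n_qtl_in_ibd = integer(0)))
    }
    do.call(rbind, lapply(split(qtls, qtls$trait), function(g) {
      data.frame(trait = g$trait[1], n_qtl = nrow(g),
                 n_qtl_in_ibd = sum(g$feature_id %in% hit_ids),
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(qtls) == 0 || nrow(segments) == 0) {
    return(list(overlaps = empty, trait_tally = tally_all(character(0))))
  }
  out <- list()
  for (ch in intersect(unique(qtls$chrom), unique(segments$chrom))) {
    q <- qtls[qtls$chrom == ch, , drop = FALSE]
    s <- segments[segments$chrom == ch, , drop = FALSE]
    qr <- IRanges::IRanges(start = q$start, end = q$end)
    sr <- IRanges::IRanges(start = s$start_bp, end = s$end_bp)
    hits <- IRanges::findOverlaps(qr, sr)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    out[[length(out) + 1L]] <- data.frame(
      qtl_id = q$feature_id[qi],
      trait = q$trait[qi],
      chrom = ch,
      ov_start = pmax(q$start[qi], s$start_bp[si]),
      ov_end = pmin(q$end[qi], s$end_bp[si]),
      pair = paste(s$sample_a[si], s$sample_b[si], sep = "|"),
      sample_a = s$sample_a[si],
      sample_b = s$sample_b[si],
      pedigree_label = pedigree_label,
      stringsAsFactors = FALSE)
  }
  overlaps <- if (length(out)) do.call(rbind, out) else empty
  overlaps <- overlaps[order(overlaps$chrom, overlaps$ov_start,
                             overlaps$qtl_id, overlaps$pair), , drop = FALSE]
  rownames(overlaps) <- NULL
  tally <- tally_all(unique(overlaps$qtl_id))
  rownames(tally) <- NULL
  list(overlaps = overlaps, trait_tally = tally)
}

#' Nominate candidate genes inside QTL-by-IBD overlaps
#'
#' Genes fully contained in an overlap interval (by default; set
#' `contained = FALSE` to accept any base-pair overlap) are listed with
#' the donor lineage of the IBD pair: the pair member that is a pedigree
#' ancestor of the other is named the donor, and every directed pedigree
#' path from donor to descendant is rendered as a transfer chain
#' (`donor>intermediate>descendant`).
#'
#' @param overlaps `overlaps` data.frame from [intersect_qtl_ibd()].
#' @param genes feature data.frame (kind "gene").
#' @param ped a [pedigree()]; `NULL` omits donor chains.
#' @param contained require full containment (default) or any overlap.
#' @return data.frame: `gene_id`, `trait`, `chrom`, `start`, `end`,
#'   `qtl_id`, `pair`, `donor`, `chain`, `pedigree_label`.
#' @export
candidate_genes <- function(overlaps, genes, ped = NULL, contained = TRUE) {
  empty <- data.frame(gene_id = character(0), trait = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), qtl_id = character(0),
                      pair = character(0), donor = character(0),
                      chain = character(0), pedigree_label = character(0))
  if (nrow(overlaps) == 0 || nrow(genes) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(overlaps))) {
    ov <- overlaps[i, ]
    g <- genes[genes$chrom == ov$chrom, , drop = FALSE]
    if (!nrow(g)) next
    inside <- if (contained) {
      g$start >= ov$ov_start & g$end <= ov$ov_end
    } else {
      g$start <= ov$ov_end & g$end >= ov$ov_start
    }
    g <- g[inside, , drop = FALSE]
    if (!nrow(g)) next
    dn <- donor_chain(ped, ov$sample_a, ov$sample_b)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g$feature_id, trait = g$trait, chrom = g$chrom,
      start = g$start, end = g$end, qtl_id = ov$qtl_id, pair = ov$pair,
      donor = dn$donor, chain = dn$chain,
      pedigree_label = ov$pedigree_label, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start, res$gene_id, res$qtl_id, res$pair), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

donor_chain <- function(ped, a, b) {
  if (is.null(ped)) return(list(donor = NA_character_, chain = NA_character_))
  known <- ped$nodes$name
  if (!a %in% known || !b %in% known) {
    return(list(donor = NA_character_, chain = NA_character_))
  }
  ab <- classify_path(ped, a, b)
  ba <- classify_path(ped, b, a)
  if (ab != "none") {
    donor <- a; desc <- b
  } else if (ba != "none") {
    donor <- b; desc <- a
  } else {
    return(list(donor = NA_character_, chain = NA_character_))
  }
  paths <- igraph::all_simple_paths(ped$graph, from = donor, to = desc,
                                    mode = "out")
  chains <- vapply(paths, function(p) paste(names(p), collapse = ">"), "")
  list(donor = donor, chain = paste(sort(chains), collapse = ";"))
}

#' Attach selection-timing quadrants to candidate genes
#'
#' Each gene is annotated with the scan window whose midpoint is nearest
#' to the gene midpoint on the same chromosome (ties broken toward the
#' lower coordinate), carrying that window's D, Hs and quadrant from
#' [classify_selection()].  Genes on chromosomes without windows are
#' left unannotated with a message.  Per-quadrant, per-trait counts are
#' returned alongside.
#'
#' @param gene_table data.frame from [candidate_genes()].
#' @param scan data.frame from [sliding_scan()].
#' @param convention quadrant convention, see [classify_selection()].
#' @return list with `genes` (input plus `window_mid_bp`, `D`, `Hs`,
#'   `quadrant`, `boundary`) and `counts` (`quadrant`, `trait`, `n`).
#' @export
selection_annotate <- function(gene_table, scan,
                               convention = c("main_text", "figure_legend")) {
  convention <- match.arg(convention)
  n <- nrow(gene_table)
  gene_table$window_mid_bp <- NA_integer_
  gene_table$D <- NA_real_
  gene_table$Hs <- NA_real_
  gene_table$quadrant <- NA_character_
  gene_table$boundary <- NA
  for (i in seq_len(n)) {
    w <- scan[scan$chrom == gene_table$chrom[i], , drop = FALSE]
    if (!nrow(w)) {
      message("selection_annotate: no scan windows on chromosome ",
              gene_table$chrom[i], "; gene ", gene_table$gene_id[i],
              " unannotated")
      next
    }
    mid <- (gene_table$start[i] + gene_table$end[i]) / 2
    dist <- abs(w$mid_bp - mid)
    # nearest window; ties -> lower coordinate
    best <- which(dist == min(dist))
    best <- best[which.min(w$mid_bp[best])]
    gene_table$window_mid_bp[i] <- w$mid_bp[best]
    gene_table$D[i] <- w$D[best]
    gene_table$Hs[i] <- w$Hs[best]
  }
  cls <- classify_selection(gene_table$D, gene_table$Hs, convention)
  gene_table$quadrant <- cls$quadrant
  gene_table$boundary <- cls$boundary
  ok <- !is.na(gene_table$quadrant)
  counts <- if (any(ok)) {
    agg <- stats::aggregate(list(n = seq_len(sum(ok))),
                            by = list(quadrant = gene_table$quadrant[ok],
                                      trait = gene_table$trait[ok]),
                            FUN = length)
    agg[order(agg$quadrant, agg$trait), , drop = FALSE]
  } else {
    data.frame(quadrant = character(0), trait = character(0), n = integer(0))
  }
  rownames(counts) <- NULL
  list(genes = gene_table, counts = counts)
}
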