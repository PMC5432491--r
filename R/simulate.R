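#' Configuration for the breeding-pedigree simulator
#'
#' Defaults emulate a scaled-down SNP-array survey of an oilseed-rape
#' breeding pedigree: 4 chromosomes of 20 Mb carrying 920 markers each
#' (46 markers per Mb, the array density of the system the simulator
#' emulates), uniform recombination at 2 cM/Mb, founder alternate-allele
#' frequencies drawn uniformly (array markers are ascertained to be
#' common), and clean calls (no genotyping error or missingness) unless
#' requested.
#'
#' @param n_chromosomes number of chromosomes; the first half (rounded up)
#'   are named A01.., the rest C01.. so both subgenomes are represented.
#' @param markers_per_chromosome markers per chromosome.
#' @param chromosome_length_bp physical length of each chromosome.
#' @param cM_per_Mb uniform recombination density.
#' @param founder_maf_range range of the uniform distribution the
#'   per-marker founder alternate-allele frequency is drawn from; use
#'   `c(0.5, 0.5)` for a fixed frequency.
#' @param genotyping_error_rate probability a reported call is flipped.
#' @param missing_rate probability a call is reported missing.
#' @param selection_targets `NULL` or a data.frame with columns
#'   `chrom`, `pos`, `founder`: at each target locus, gametes are
#'   resampled during every cross until the offspring carries the favored
#'   founder's allele copy (directional selection by gamete rejection).
#' @param seed integer RNG seed recorded in outputs.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4L,
                       markers_per_chromosome = 920L,
                       chromosome_length_bp = 20e6,
                       cM_per_Mb = 2,
                       founder_maf_range = c(0.1, 0.9),
                       genotyping_error_rate = 0,
                       missing_rate = 0,
                       selection_targets = NULL,
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 2,
            chromosome_length_bp > 0, cM_per_Mb >= 0,
            length(founder_maf_range) == 2,
            all(founder_maf_range >= 0 & founder_maf_range <= 1),
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(selection_targets)) {
    stopifnot(is.data.frame(selection_targets),
              all(c("chrom", "pos", "founder") %in% names(selection_targets)))
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 chromosome_length_bp = as.numeric(chromosome_length_bp),
                 cM_per_Mb = as.numeric(cM_per_Mb),
                 founder_maf_range = as.numeric(founder_maf_range),
                 genotyping_error_rate = as.numeric(genotyping_error_rate),
                 missing_rate = as.numeric(missing_rate),
                 selection_targets = selection_targets,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_chrom_names <- function(n) {
  na <- ceiling(n / 2)
  c(sprintf("A%02d", seq_len(na)), sprintf("C%02d", seq_len(n - na)))
}

#' Simulate founder lines
#'
#' Generates a marker map and mutually homozygous founder genotypes.
#' Per-marker alternate-allele frequencies q are drawn from the configured
#' uniform range; each founder's allele is an independent Bernoulli(q)
#' draw, fixed to homozygosity.
#'
#' @param config a [sim_config()].
#' @param founder_names character vector of founder line names.
#' @return list with `calls` (founders x markers integer matrix) and
#'   `map` (a [marker_map()]).
#' @export
simulate_founders <- function(config, founder_names) {
  set.seed(config$seed)
  chroms <- sim_chrom_names(config$n_chromosomes)
  m <- config$markers_per_chromosome
  maps <- lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chromosome_length_bp, m))
    data.frame(marker_id = sprintf("%s_m%05d", ch, seq_len(m)),
               chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  mapdf <- do.call(rbind, maps)
  map <- marker_map(mapdf$marker_id, mapdf$chrom, mapdf$pos)
  nmark <- nrow(map)
  q <- stats::runif(nmark, config$founder_maf_range[1],
                    config$founder_maf_range[2])
  calls <- t(vapply(founder_names,
                    function(f) stats::rbinom(nmark, 1L, q),
                    integer(nmark)))
  dimnames(calls) <- list(founder_names, map$marker_id)
  storage.mode(calls) <- "integer"
  list(calls = calls, map = map, q = q)
}

# one recombinant doubled-haploid gamete from two parental haplotypes.
# crossover count ~ Poisson(chromosome length in Morgans), breakpoints
# uniform in genetic distance (uniform bp under constant cM/Mb).
# Returns logical vector: TRUE where the allele comes from the mother.
recombinant_choice <- function(map_pos, chrom_len_bp, cM_per_Mb) {
  morgans <- chrom_len_bp / 1e6 * cM_per_Mb / 100
  n_xo <- stats::rpois(1L, morgans)
  from_mother <- stats::runif(1) < 0.5
  if (n_xo == 0) return(rep(from_mother, length(map_pos)))
  bp <- sort(stats::runif(n_xo, 0, chrom_len_bp))
  # parity of crossovers left of each marker decides the source haplotype
  k <- findInterval(map_pos, bp)
  xor(from_mother, k %% 2 == 1)
}

#' Simulate one cross to a doubled-haploid offspring
#'
#' Crosses two homozygous lines, draws one recombinant gamete per
#' chromosome from the F1, and fixes it to homozygosity (the
#' doubled-haploid endpoint).  Ancestry bookkeeping is spliced from the
#' parents at the same breakpoints, so every offspring allele traces to
#' exactly one founder copy.
#'
#' @param mother,father names of the parent lines.
#' @param state simulation state as built by [simulate_pedigree()]:
#'   list with `calls`, `founder_origin`, `donor` matrices and `map`,
#'   each keyed by line name.
#' @param config a [sim_config()].
#' @return list with vectors `calls` (integer), `founder_origin`
#'   (character), `donor` (character, immediate parent per marker).
#' @export
simulate_cross <- function(mother, father, state, config) {
  map <- state$map
  nmark <- nrow(map)
  calls <- integer(nmark)
  origin <- character(nmark)
  donor <- character(nmark)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    from_mother <- recombinant_choice(map$pos[idx],
                                      config$chromosome_length_bp,
                                      config$cM_per_Mb)
    src <- ifelse(from_mother, mother, father)
    calls[idx] <- ifelse(from_mother,
                         state$calls[mother, idx],
                         state$calls[father, idx])
    origin[idx] <- ifelse(from_mother,
                          state$founder_origin[mother, idx],
                          state$founder_origin[father, idx])
    donor[idx] <- src
  }
  list(calls = as.integer(calls), founder_origin = origin, donor = donor)
}

#' Forward-simulate a breeding pedigree of inbred lines
#'
#' Simulates founder genotypes, then performs every documented cross in
#' topological order, producing a doubled-haploid offspring per cross
#' with exact founder-origin tracking.  Directional selection is applied
#' by gamete rejection: at each configured target locus, if either parent
#' carries the favored founder's allele copy, the cross is redrawn until
#' the offspring carries it.  Genotyping error then flips observed calls
#' at `genotyping_error_rate`, missingness is applied last, and lines
#' tagged as diploid A-genome species get all-missing C-subgenome
#' columns.
#'
#' @param ped a [pedigree()]; every non-founder must have two parents.
#' @param config a [sim_config()].
#' @return An object of class `pedsim`: list with
#'   \describe{
#'     \item{calls}{observed genotype matrix (error/missingness applied).}
#'     \item{true_calls}{error-free genotype matrix.}
#'     \item{founder_origin}{character matrix lines x markers, the founder
#'       whose allele copy each line carries.}
#'     \item{donor}{character matrix, immediate parent each allele came
#'       from (`NA` for founders).}
#'     \item{map, ped, config}{inputs.}
#'   }
#' @export
simulate_pedigree <- function(ped, config) {
  fnd <- founders(ped)
  sim <- simulate_founders(config, fnd)
  map <- sim$map
  nmark <- nrow(map)
  lines <- ped$nodes$name
  ord <- igraph::topo_sort(ped$graph, mode = "out")
  ord <- names(ord)

  targets <- resolve_targets(config$selection_targets, map)

  calls <- matrix(NA_integer_, length(lines), nmark,
                  dimnames = list(lines, map$marker_id))
  origin <- matrix(NA_character_, length(lines), nmark,
                   dimnames = list(lines, map$marker_id))
  donor <- matrix(NA_character_, length(lines), nmark,
                  dimnames = list(lines, map$marker_id))
  calls[fnd, ] <- sim$calls[fnd, ]
  for (f in fnd) origin[f, ] <- f

  state <- list(calls = calls, founder_origin = origin, donor = donor,
                map = map)
  for (node in ord) {
    if (node %in% fnd) next
    par <- ped$edges$parent[ped$edges$offspring == node]
    if (length(par) != 2) {
      stop("non-founder '", node, "' must have exactly two documented parents")
    }
    off <- simulate_cross(par[1], par[2], state, config)
    if (nrow(targets)) {
      for (t in seq_len(nrow(targets))) {
        ti <- targets$marker_index[t]
        fav <- targets$founder[t]
        parent_carries <- state$founder_origin[par[1], ti] == fav ||
          state$founder_origin[par[2], ti] == fav
        tries <- 0L
        while (isTRUE(parent_carries) && off$founder_origin[ti] != fav) {
          off <- simulate_cross(par[1], par[2], state, config)
          tries <- tries + 1L
          if (tries > 10000L) stop("selection resampling did not converge")
        }
      }
    }
    state$calls[node, ] <- off$calls
    state$founder_origin[node, ] <- off$founder_origin
    state$donor[node, ] <- off$donor
  }

  observed <- state$calls
  if (config$genotyping_error_rate > 0) {
    flip <- matrix(stats::runif(length(observed)) < config$genotyping_error_rate,
                   nrow(observed))
    flip[is.na(observed)] <- FALSE
    observed[flip] <- 1L - observed[flip]
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(observed)) < config$missing_rate,
                   nrow(observed))
    observed[miss] <- NA_integer_
  }
  dipA <- ped$nodes$name[ped$nodes$species == "A"]
  if (length(dipA)) {
    ccols <- subgenome(map$chrom) == "C"
    observed[dipA, ccols] <- NA_integer_
  }
  structure(list(calls = observed,
                 true_calls = state$calls,
                 founder_origin = state$founder_origin,
                 donor = state$donor,
                 map = map, ped = ped, config = config),
            class = "pedsim")
}

resolve_targets <- function(targets, map) {
  if (is.null(targets) || nrow(targets) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      founder = character(0), marker_index = integer(0)))
  }
  idx <- integer(nrow(targets))
  for (t in seq_len(nrow(targets))) {
    on <- which(map$chrom == targets$chrom[t])
    if (!length(on)) stop("selection target chromosome not in map: ",
                          targets$chrom[t])
    if (targets$pos[t] < 1 || targets$pos[t] > max(map$pos[on])) {
      stop("selection target position outside map on ", targets$chrom[t])
    }
    idx[t] <- on[which.min(abs(map$pos[on] - targets$pos[t]))]
  }
  cbind(targets, marker_index = idx)
}

#' @export
print.pedsim <- function(x, ...) {
  cat("pedsim:", nrow(x$calls), "lines x", ncol(x$calls), "markers on",
      length(unique(x$map$chrom)), "chromosomes (seed ",
      x$config$seed, ")\n", sep = " ")
  invisible(x)
}

# For every marker, does `line`'s transmission chain pass through `node`?
# Follows the donor (immediate parent) matrix up to the founders.
lineage_through <- function(sim, line, node) {
  nmark <- ncol(sim$donor)
  if (line == node) return(rep(TRUE, nmark))
  through <- rep(FALSE, nmark)
  cur <- rep(line, nmark)
  idx <- seq_len(nmark)
  repeat {
    cur <- sim$donor[cbind(match(cur, rownames(sim$donor)), idx)]
    alive <- !is.na(cur)
    if (!any(alive)) break
    idx <- idx[alive]
    cur <- cur[alive]
    through[idx[cur == node]] <- TRUE
  }
  through
}

#' Ground-truth IBD segments from simulated ancestry
#'
#' Extracts maximal marker runs that are identical by descent according
#' to the simulator's exact bookkeeping.  Two notions are available:
#' `mode = "lineage"` marks markers whose transmission chain from
#' `b` (the descendant) passes through `a` (the ancestor);
#' `mode = "shared_founder"` marks markers where the two lines carry the
#' same founder's allele copy (the pairwise truth used to score the
#' detector).
#'
#' @param sim a `pedsim` from [simulate_pedigree()].
#' @param a,b line names; for `"lineage"`, `a` is the ancestor and `b`
#'   the descendant.
#' @param mode `"lineage"` or `"shared_founder"`.
#' @return a segment data.frame as from [ibd_segments()].
#' @export
true_ibd_segments <- function(sim, a, b,
                              mode = c("shared_founder", "lineage")) {
  mode <- match.arg(mode)
  stopifnot(a %in% rownames(sim$calls), b %in% rownames(sim$calls))
  shared <- if (mode == "lineage") {
    lineage_through(sim, b, a)
  } else {
    sim$founder_origin[a, ] == sim$founder_origin[b, ]
  }
  map <- sim$map
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    r <- rle(shared[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = map$pos[idx[starts[k]]],
        end_bp = map$pos[idx[ends[k]]],
        n_markers = r$lengths[k])
    }
  }
  if (!length(out)) {
    return(ibd_segments(character(0), character(0), character(0),
                        integer(0), integer(0)))
  }
  df <- do.call(rbind, out)
  ibd_segments(a, b, df$chrom, df$start_bp, df$end_bp, df$n_markers, 0L)
}

#' Realized genome fraction a descendant inherited from an ancestor
#'
#' The fraction of markers whose transmission chain passes through the
#' ancestor, from the simulator's exact ancestry tracks.  Over replicates
#' this converges to [expected_contribution()].
#'
#' @param sim a `pedsim`.
#' @param ancestor,descendant line names.
#' @return fraction in `[0, 1]`.
#' @export
realized_contribution <- function(sim, ancestor, descendant) {
  mean(lineage_through(sim, descendant, ancestor))
}
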