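#' Build a breeding pedigree graph
#'
#' A pedigree is a directed acyclic graph of cultivars: each edge points
#' from a parent to an offspring of a documented cross and carries a
#' breeding-cycle index.  Nodes may be tagged with a species/genome label
#' ("AC" for allotetraploid *B. napus*, "A" for diploid *B. rapa*, whose
#' C-subgenome data are structurally missing).
#'
#' @param parent,offspring character vectors defining directed edges.
#' @param cycle integer breeding-cycle index per edge (default 1).
#' @param species optional named character vector, names = node names,
#'   values in `c("AC", "A")`; unnamed nodes default to "AC".
#' @return An object of class `pedigree`: list with `edges` (data.frame
#'   `parent`, `offspring`, `cycle`), `nodes` (data.frame `name`,
#'   `species`), and `graph` (igraph).
#' @export
pedigree <- function(parent, offspring, cycle = 1L, species = NULL) {
  edges <- data.frame(parent = as.character(parent),
                      offspring = as.character(offspring),
                      cycle = as.integer(rep_len(cycle, length(parent))),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("parent", "offspring")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) {
    cyc <- find_one_cycle(edges)
    stop("pedigree contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  np <- table(edges$offspring)
  if (any(np > 2)) {
    stop("offspring with more than two parents: ",
         paste(names(np)[np > 2], collapse = ", "))
  }
  nodes <- data.frame(name = igraph::V(g)$name, stringsAsFactors = FALSE)
  nodes$species <- "AC"
  if (!is.null(species)) {
    hit <- intersect(names(species), nodes$name)
    nodes$species[match(hit, nodes$name)] <- unname(species[hit])
  }
  structure(list(edges = edges, nodes = nodes, graph = g),
            class = "pedigree")
}

# walk successors until a node repeats; graphs here are tiny
find_one_cycle <- function(edges) {
  succ <- split(edges$offspring, edges$parent)
  for (start in unique(edges$parent)) {
    path <- start
    cur <- start
    repeat {
      nxt <- succ[[cur]]
      if (is.null(nxt)) break
      cur <- nxt[[1]]
      if (cur %in% path) return(c(path[which(path == cur):length(path)], cur))
      path <- c(path, cur)
    }
  }
  character(0)
}

#' Read a pedigree from a CSV edge list
#'
#' Expects a header `parent,offspring,cycle` (cycle optional).
#'
#' @param path CSV path.
#' @param species optional named species vector, see [pedigree()].
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path, species = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("parent", "offspring") %in% names(df))) {
    stop("pedigree CSV needs 'parent' and 'offspring' columns")
  }
  cyc <- if ("cycle" %in% names(df)) df$cycle else 1L
  pedigree(df$parent, df$offspring, cyc, species = species)
}

#' Write a pedigree edge list to CSV
#' @param ped a [pedigree()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x$nodes), "cultivars,", nrow(x$edges), "cross edges\n")
  cat("founders:", paste(founders(x), collapse = ", "), "\n")
  invisible(x)
}

#' Founders of a pedigree
#'
#' Founders are the in-degree-zero nodes: cultivars whose own parents are
#' not documented in the pedigree.
#'
#' @param ped a [pedigree()].
#' @return character vector of founder names.
#' @export
founders <- function(ped) {
  deg <- igraph::degree(ped$graph, mode = "in")
  sort(names(deg)[deg == 0])
}

#' Final cultivars (sinks) of a pedigree
#' @param ped a [pedigree()].
#' @return character vector of out-degree-zero node names.
#' @export
final_cultivars <- function(ped) {
  deg <- igraph::degree(ped$graph, mode = "out")
  sort(names(deg)[deg == 0])
}

#' Classify an ancestor-to-descendant transfer path
#'
#' Haplotype transfer from an ancestor to a descendant cultivar is
#' *direct* when a single parent-to-offspring cross edge connects them
#' (even if additional longer routes exist), *indirect* when the only
#' connection is a directed path through intermediate cultivars of two or
#' more crosses, and *none* when no directed path exists (including the
#' reversed direction).
#'
#' @param ped a [pedigree()].
#' @param ancestor,descendant node names; must differ.
#' @return one of `"direct"`, `"indirect"`, `"none"`.
#' @export
classify_path <- function(ped, ancestor, descendant) {
  nodes <- ped$nodes$name
  if (!ancestor %in% nodes) stop("unknown pedigree node: ", ancestor)
  if (!descendant %in% nodes) stop("unknown pedigree node: ", descendant)
  if (ancestor == descendant) stop("ancestor and descendant must differ")
  e <- ped$edges
  if (any(e$parent == ancestor & e$offspring == descendant)) return("direct")
  d <- igraph::distances(ped$graph, v = ancestor, to = descendant,
                         mode = "out")
  if (is.finite(d[1, 1])) "indirect" else "none"
}

#' Expected genetic contribution of an ancestor
#'
#' The theoretical fraction of a descendant's genome inherited from an
#' ancestor under Mendelian expectation, ignoring selection and
#' undocumented parents: each cross halves the expected contribution, so
#' the value is the sum over all directed pedigree paths of
#' `(1/2)^(number of edges)`.  A parent contributes 0.5, a grandparent
#' reachable by one path 0.25.
#'
#' @param ped a [pedigree()].
#' @param ancestor,descendant node names.
#' @return a fraction in `[0, 1]`; 0 when no path exists.
#' @export
expected_contribution <- function(ped, ancestor, descendant) {
  nodes <- ped$nodes$name
  if (!ancestor %in% nodes || !descendant %in% nodes) {
    stop("unknown pedigree node")
  }
  if (ancestor == descendant) return(1)
  paths <- igraph::all_simple_paths(ped$graph, from = ancestor,
                                    to = descendant, mode = "out")
  if (!length(paths)) return(0)
  sum(vapply(paths, function(p) 0.5 ^ (length(p) - 1), numeric(1)))
}

#' All ancestors of a node
#' @param ped a [pedigree()].
#' @param node node name.
#' @return character vector of ancestor names (excluding the node).
#' @export
ancestors <- function(ped, node) {
  if (!node %in% ped$nodes$name) stop("unknown pedigree node: ", node)
  reach <- igraph::subcomponent(ped$graph, node, mode = "in")
  setdiff(names(reach), node)
}

#' Per-pedigree cultivar panels
#'
#' For each final cultivar (sink), the panel of lines used in diversity
#' scans: the cultivar plus all of its documented ancestors.
#'
#' @param ped a [pedigree()].
#' @return named list of character vectors, one per final cultivar.
#' @export
pedigree_panels <- function(ped) {
  fins <- final_cultivars(ped)
  stats::setNames(lapply(fins, function(f) sort(c(f, ancestors(ped, f)))),
                  fins)
}

#' The two-pedigree breeding history of Tapidor and Ningyou7
#'
#' The documented crosses behind the European winter cultivar Tapidor
#' (Liho x Bronowski -> Regent; Regent x Bienvenu -> Tapidor) and the
#' Chinese semi-winter cultivar Ningyou7 (Shengliyoucai x Chengduai ->
#' Chuanyou2; Chuanyou2 x Ningyou1 -> Ningyou7).  Chengduai is diploid
#' *B. rapa* (A genome only).  Undocumented contributors (Turret, SI8879,
#' the parents of Ningyou1) are not represented.
#'
#' @return a [pedigree()] with both pedigrees as disconnected components.
#' @export
tapidor_ningyou_pedigree <- function() {
  pedigree(
    parent    = c("Liho", "Bronowski", "Regent", "Bienvenu",
                  "Shengliyoucai", "Chengduai", "Chuanyou2", "Ningyou1"),
    offspring = c("Regent", "Regent", "Tapidor", "Tapidor",
                  "Chuanyou2", "Chuanyou2", "Ningyou7", "Ningyou7"),
    cycle     = c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L),
    species   = c(Chengduai = "A")
  )
}
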