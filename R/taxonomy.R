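## Taxonomy construction, NCBI-dump / TSV I/O, LCA and clade queries.

normalizeRank <- function(rank) {
  rank <- tolower(trimws(rank))
  ifelse(rank %in% MAJOR_RANKS, rank, "no-rank")
}

computeDepths <- function(taxon_id, parent_id) {
  n <- length(taxon_id)
  idx <- match(parent_id, taxon_id)
  depth <- rep(NA_integer_, n)
  root <- which(taxon_id == parent_id)
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root (its own parent)")
  depth[root] <- 0L
  ## peel the tree level by level; a leftover node implies a cycle
  frontier <- root
  while (length(frontier)) {
    children <- which(idx %in% frontier & is.na(depth))
    depth[children] <- depth[idx[children]] + 1L
    frontier <- children
  }
  if (anyNA(depth))
    stop("cycle detected: nodes ",
         paste(utils::head(taxon_id[is.na(depth)], 5), collapse = ", "),
         " never reach the root")
  names(depth) <- as.character(taxon_id)
  depth
}

#' Construct a Taxonomy from a node table
#'
#' @param nodes data.frame with columns \code{taxon_id}, \code{parent_id},
#'   \code{rank} and optionally \code{name}. Ranks outside the seven major
#'   ranks are mapped to \code{"no-rank"}.
#' @return A [Taxonomy] object.
#' @examples
#' tax <- Taxonomy(data.frame(taxon_id = 1:3, parent_id = c(1, 1, 2),
#'                            rank = c("no-rank", "superkingdom", "phylum")))
#' nTaxa(tax)
#' @export
Taxonomy <- function(nodes) {
  nodes$taxon_id <- as.integer(nodes$taxon_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$rank <- normalizeRank(nodes$rank)
  if (is.null(nodes$name))
    nodes$name <- paste0("taxon_", nodes$taxon_id)
  dangling <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(dangling))
    stop("integrity error: parent id(s) ",
         paste(utils::head(dangling, 5), collapse = ", "),
         " not present in the taxonomy")
  depth <- computeDepths(nodes$taxon_id, nodes$parent_id)
  root <- nodes$taxon_id[nodes$taxon_id == nodes$parent_id]
  rownames(nodes) <- as.character(nodes$taxon_id)
  new("Taxonomy", nodes = nodes[c("taxon_id", "parent_id", "rank", "name")],
      rootId = as.integer(root), depth = depth)
}

#' @describeIn Taxonomy number of nodes in the taxonomy.
#' @param taxonomy A [Taxonomy].
#' @export
nTaxa <- function(taxonomy) nrow(taxonomy@nodes)

#' Accessors for Taxonomy node attributes
#'
#' @param taxonomy A [Taxonomy].
#' @param taxa integer taxon ids (all nodes when missing).
#' @return Named vector of the requested attribute.
#' @export
taxonRank <- function(taxonomy, taxa = taxonomy@nodes$taxon_id) {
  stats::setNames(taxonomy@nodes[as.character(taxa), "rank"],
                  as.character(taxa))
}

#' @rdname taxonRank
#' @export
taxonParent <- function(taxonomy, taxa = taxonomy@nodes$taxon_id) {
  stats::setNames(taxonomy@nodes[as.character(taxa), "parent_id"],
                  as.character(taxa))
}

#' @rdname taxonRank
#' @export
taxonName <- function(taxonomy, taxa = taxonomy@nodes$taxon_id) {
  stats::setNames(taxonomy@nodes[as.character(taxa), "name"],
                  as.character(taxa))
}

#' @rdname taxonRank
#' @export
taxonDepth <- function(taxonomy, taxa = taxonomy@nodes$taxon_id) {
  taxonomy@depth[as.character(taxa)]
}

#' @rdname taxonRank
#' @export
rootId <- function(taxonomy) taxonomy@rootId

setMethod("show", "Taxonomy", function(object) {
  rk <- table(object@nodes$rank)
  cat("Taxonomy with", nrow(object@nodes), "nodes (root",
      object@rootId, ")\n")
  cat("  ranks:", paste(names(rk), rk, sep = ":", collapse = " "), "\n")
})

.checkKnown <- function(taxonomy, taxa) {
  unknown <- setdiff(taxa, taxonomy@nodes$taxon_id)
  if (length(unknown))
    stop("lookup error: unknown taxon id(s) ",
         paste(utils::head(unknown, 5), collapse = ", "))
}

#' Ancestor path from a node up to the root
#'
#' @param taxonomy A [Taxonomy].
#' @param taxon A single taxon id.
#' @return Integer vector of taxon ids from \code{taxon} up to the root
#'   (inclusive at both ends).
#' @export
ancestorPath <- function(taxonomy, taxon) {
  .checkKnown(taxonomy, taxon)
  parent <- taxonomy@nodes$parent_id
  ids <- taxonomy@nodes$taxon_id
  path <- integer(taxonomy@depth[as.character(taxon)] + 1L)
  cur <- as.integer(taxon)
  for (i in seq_along(path)) {
    path[i] <- cur
    cur <- parent[match(cur, ids)]
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is an ancestor-or-self of every input
#' taxon. The result is a set function: duplicated ids and input order do
#' not matter, and \code{lca(c(S, lca(S))) == lca(S)}.
#'
#' @param taxonomy A [Taxonomy].
#' @param taxa Non-empty vector of taxon ids present in the taxonomy.
#' @return A single taxon id.
#' @examples
#' tax <- makeSyntheticTaxonomy(8, seed = 1)
#' sp <- speciesIds(tax)
#' lca(tax, sp[1])        # singleton: the node itself
#' lca(tax, sp)           # all species: an ancestor of every leaf
#' @export
lca <- function(taxonomy, taxa) {
  taxa <- unique(as.integer(taxa))
  if (!length(taxa)) stop("argument error: empty taxon set")
  .checkKnown(taxonomy, taxa)
  if (length(taxa) == 1L) return(taxa)
  depth <- taxonomy@depth
  parent <- taxonomy@nodes$parent_id
  ids <- taxonomy@nodes$taxon_id
  ## walk all nodes up in lock step until they coincide
  cur <- taxa
  repeat {
    if (length(unique(cur)) == 1L) return(cur[1])
    d <- depth[as.character(cur)]
    deepest <- d == max(d)
    cur[deepest] <- parent[match(cur[deepest], ids)]
    cur <- unique(cur)
  }
}

#' Clade membership test
#'
#' @param taxonomy A [Taxonomy].
#' @param taxon Taxon id(s) to test (vectorised).
#' @param cladeRoot A single taxon id.
#' @return Logical: is \code{cladeRoot} an ancestor-or-self of
#'   \code{taxon}?
#' @export
isInClade <- function(taxonomy, taxon, cladeRoot) {
  .checkKnown(taxonomy, c(taxon, cladeRoot))
  members <- subtreeTaxa(taxonomy, cladeRoot)
  as.integer(taxon) %in% members
}

#' All taxa inside a clade (the clade root and its descendants)
#'
#' @param taxonomy A [Taxonomy].
#' @param cladeRoot One or more clade-root taxon ids.
#' @return Integer vector of member taxon ids.
#' @export
subtreeTaxa <- function(taxonomy, cladeRoot) {
  .checkKnown(taxonomy, cladeRoot)
  cladeRoot <- as.integer(cladeRoot)
  ids <- taxonomy@nodes$taxon_id
  parent <- taxonomy@nodes$parent_id
  inside <- ids %in% cladeRoot
  repeat {
    grown <- inside | (parent %in% ids[inside] & ids != parent)
    if (identical(grown, inside)) break
    inside <- grown
  }
  ids[inside]
}

#' Species-rank taxon ids of a taxonomy
#'
#' @param taxonomy A [Taxonomy].
#' @return Integer vector of all nodes with rank "species".
#' @export
speciesIds <- function(taxonomy) {
  taxonomy@nodes$taxon_id[taxonomy@nodes$rank == "species"]
}

#' Nearest ranked ancestor of a node
#'
#' Maps a node to itself if it carries a major rank, otherwise to its
#' closest ancestor that does; the root maps to itself even when unranked.
#'
#' @param taxonomy A [Taxonomy].
#' @param taxa Taxon id(s), vectorised.
#' @return Integer vector of ranked node ids (or the root).
#' @export
nearestRankedAncestor <- function(taxonomy, taxa) {
  .checkKnown(taxonomy, taxa)
  vapply(as.integer(taxa), function(t) {
    repeat {
      if (taxonomy@nodes[as.character(t), "rank"] != "no-rank" ||
          t == taxonomy@rootId)
        return(t)
      t <- taxonomy@nodes[as.character(t), "parent_id"]
    }
  }, integer(1))
}

## ---- I/O ------------------------------------------------------------------

#' Read a taxonomy from NCBI taxdump files or a simplified TSV
#'
#' Two dialects are accepted and auto-detected per file. The NCBI taxdump
#' dialect is tab-pipe-tab delimited (\code{nodes.dmp}: taxon id, parent id,
#' rank in the first three fields; \code{names.dmp} filtered to rows whose
#' name class is "scientific name"). The simplified dialect is a headerless
#' 3- or 4-column TSV: taxon id, parent id, rank, optional name.
#'
#' @param nodesPath Path to the nodes file.
#' @param namesPath Optional path to a names file (taxdump dialect).
#' @return A [Taxonomy].
#' @export
readTaxonomy <- function(nodesPath, namesPath = NULL) {
  lines <- readLines(nodesPath)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: empty nodes file")
  dump <- grepl("\t|\t", lines[1], fixed = TRUE)
  split1 <- function(l) {
    if (dump) strsplit(sub("\t\\|$", "", l), "\t|\t", fixed = TRUE)[[1]]
    else strsplit(l, "\t", fixed = TRUE)[[1]]
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- split1(lines[i])
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[1]))) ||
        is.na(suppressWarnings(as.integer(f[2]))))
      stop("parse error in nodes file, line ", i, ": ", lines[i])
    list(taxon_id = as.integer(f[1]), parent_id = as.integer(f[2]),
         rank = f[3], name = if (length(f) >= 4L && !dump) f[4] else NA)
  })
  nodes <- data.frame(
    taxon_id = vapply(rows, `[[`, integer(1), "taxon_id"),
    parent_id = vapply(rows, `[[`, integer(1), "parent_id"),
    rank = vapply(rows, `[[`, character(1), "rank"),
    name = vapply(rows, function(r) as.character(r$name), character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(namesPath)) {
    nl <- readLines(namesPath)
    nl <- nl[nzchar(trimws(nl))]
    nf <- lapply(nl, function(l)
      strsplit(sub("\t\\|$", "", l), "\t|\t", fixed = TRUE)[[1]])
    sci <- vapply(nf, function(f)
      length(f) >= 4L && trimws(f[4]) == "scientific name", logical(1))
    nm <- stats::setNames(vapply(nf[sci], `[`, character(1), 2),
                          vapply(nf[sci], `[`, character(1), 1))
    hit <- as.character(nodes$taxon_id) %in% names(nm)
    nodes$name[hit] <- unname(nm[as.character(nodes$taxon_id[hit])])
  }
  nodes$name[is.na(nodes$name)] <- paste0("taxon_",
                                          nodes$taxon_id[is.na(nodes$name)])
  Taxonomy(nodes)
}

#' Write a taxonomy as a simplified 4-column TSV
#'
#' @param taxonomy A [Taxonomy].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy@nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate a random ranked taxonomy
#'
#' Builds a tree with the seven major ranks by grouping species into
#' genera, genera into families, and so on up to superkingdoms under an
#' unranked root. Group sizes are random but the species count is exact, so
#' rank sequences along root-to-leaf paths never repeat a major rank.
#'
#' @param nSpecies Number of species leaves.
#' @param meanChildren Average group size when collapsing one rank into the
#'   next (default 3).
#' @param seed Optional integer seed for reproducibility.
#' @return A [Taxonomy] whose leaves are the species.
#' @export
makeSyntheticTaxonomy <- function(nSpecies, meanChildren = 3, seed = NULL) {
  withSeed(seed, {
    ranks <- rev(MAJOR_RANKS)   # species first, superkingdom last
    nextId <- 2L
    newIds <- function(n) {
      ids <- seq.int(nextId, length.out = n)
      nextId <<- nextId + n
      as.integer(ids)
    }
    nodes <- data.frame(taxon_id = 1L, parent_id = 1L, rank = "no-rank",
                        name = "root", stringsAsFactors = FALSE)
    level <- newIds(nSpecies)
    nodes <- rbind(nodes, data.frame(
      taxon_id = level, parent_id = NA_integer_, rank = "species",
      name = paste0("species_", seq_len(nSpecies))))
    for (rank in ranks[-1]) {
      nGroups <- if (rank == "superkingdom") min(2L, length(level))
                 else max(1L, round(length(level) / meanChildren))
      nGroups <- min(nGroups, length(level))
      grp <- sort(sample(rep_len(seq_len(nGroups), length(level))))
      parents <- newIds(nGroups)
      nodes$parent_id[match(level, nodes$taxon_id)] <- parents[grp]
      nodes <- rbind(nodes, data.frame(
        taxon_id = parents, parent_id = NA_integer_, rank = rank,
        name = paste0(rank, "_", seq_len(nGroups))))
      level <- parents
    }
    nodes$parent_id[match(level, nodes$taxon_id)] <- 1L
    Taxonomy(nodes)
  })
}
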