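# 16S rRNA distance phylogeny: JC69 distances with gap/N-aware site
# filtering, neighbor-joining via ape, bootstrap bipartition support, and
# outgroup rooting / Newick round-trips.

#' Read an aligned FASTA file as a multiple alignment
#'
#' @param path Aligned DNA FASTA (rows must be equal length; `-` for gaps).
#' @return A tibble `taxon`, `sequence`.
#' @export
read_alignment <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  aln <- tibble::tibble(taxon = sub("\\s.*$", "", names(raw)),
                        sequence = toupper(as.character(raw)))
  .validate_alignment(aln)
  aln
}

.validate_alignment <- function(aln) {
  stopifnot(nrow(aln) >= 3, !anyDuplicated(aln$taxon))
  if (length(unique(nchar(aln$sequence))) != 1) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  invisible(aln)
}

#' Jukes-Cantor (JC69) distance matrix from an alignment
#'
#' For each pair, columns where either row holds a gap or `N` are excluded;
#' `p` is the mismatch fraction over the remaining columns and
#' `d = -(3/4) * ln(1 - (4/3) * p)`. Saturated pairs (`p >= 3/4`) receive a
#' configurable ceiling distance with a warning rather than an error, so
#' bootstrap replicates remain runnable.
#'
#' @param aln Alignment tibble (`taxon`, `sequence`) from
#'   [read_alignment()] or [evolve_alignment()].
#' @param model `"jc69"` (default) or `"p"` for the raw p-distance.
#' @param saturation_ceiling Distance assigned to saturated pairs
#'   (default 5).
#' @return A symmetric numeric matrix with taxa as dimnames.
#' @export
jc69_distance <- function(aln, model = c("jc69", "p"),
                          saturation_ceiling = 5) {
  model <- match.arg(model)
  .validate_alignment(aln)
  n <- nrow(aln)
  chars <- do.call(rbind, strsplit(aln$sequence, ""))
  valid <- matrix(chars %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(aln$taxon, aln$taxon))
  saturated <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- valid[i, ] & valid[j, ]
      if (!any(comp)) {
        stop("no comparable columns between '", aln$taxon[i], "' and '",
             aln$taxon[j], "'", call. = FALSE)
      }
      p <- sum(chars[i, comp] != chars[j, comp]) / sum(comp)
      if (model == "p") {
        dij <- p
      } else if (p >= 0.75) {
        dij <- saturation_ceiling
        saturated <- TRUE
      } else {
        dij <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (saturated) {
    warning("saturated pair(s) set to the ceiling distance ",
            saturation_ceiling, call. = FALSE)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`); negative branch lengths are
#' clamped to zero, which is standard practice for NJ output.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the full-data NJ tree
#'
#' Resamples alignment columns with replacement `replicates` times, rebuilds
#' the NJ tree per replicate, and attaches to each internal edge of the
#' full-data tree the fraction of replicate trees containing the same
#' bipartition (stored in `$node.label`). An alignment of identical
#' sequences carries no signal; by convention all supports are then 1 (with
#' a warning about the star-tree situation). Deterministic given `seed`.
#'
#' @param aln Alignment tibble.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @param model Distance model, as in [jc69_distance()].
#' @return The full-data `phylo` tree with supports in `$node.label`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L,
                              model = "jc69") {
  stopifnot(replicates >= 1)
  .validate_alignment(aln)
  if (length(unique(aln$sequence)) == 1) {
    warning("all sequences identical: star tree, supports set to 1",
            call. = FALSE)
    tr <- nj_tree(matrix(1e-8, nrow(aln), nrow(aln),
                         dimnames = list(aln$taxon, aln$taxon)) -
                    diag(1e-8, nrow(aln)))
    tr$node.label <- rep("1", tr$Nnode)
    return(tr)
  }
  full <- nj_tree(jc69_distance(aln, model))
  L <- nchar(aln$sequence[1])
  chars <- do.call(rbind, strsplit(aln$sequence, ""))
  reps <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- aln
      res$sequence <- apply(chars[, cols, drop = FALSE], 1, paste,
                            collapse = "")
      tryCatch(nj_tree(suppressWarnings(jc69_distance(res, model))),
               error = function(e) NULL)
    })
  })
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / length(reps)
  full$node.label <- as.character(signif(support, 3))
  attr(full, "support") <- support
  full
}

#' Root a tree on an outgroup taxon
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup Taxon label to root on.
#' @return A rooted `phylo` tree; bipartitions are unchanged.
#' @export
root_on <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("unknown outgroup taxon: '", outgroup, "'", call. = FALSE)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Write / read a tree in Newick format
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`; supports are
#' carried as internal node labels, branch lengths with `:`.
#'
#' @param tree A `phylo` tree.
#' @param path File path.
#' @return `path` invisibly / the parsed `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
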