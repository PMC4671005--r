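#' Construct a tagged gene-set collection
#'
#' @param sets named list of character vectors (gene ids), all nonempty.
#' @param category one of `chromosomal_location`, `pathway`,
#'   `motif_TF_miRNA`, `GO`, `signature`.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, category = c("GO", "pathway",
                                                   "chromosomal_location",
                                                   "motif_TF_miRNA",
                                                   "signature")) {
  category <- match.arg(category)
  if (length(sets) == 0 || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a nonempty named list")
  if (any(vapply(sets, length, 0L) == 0)) stop("empty gene set in collection")
  structure(lapply(sets, unique), class = "gene_set_collection",
            category = category)
}

#' Category tag of a collection
#' @param collection a `gene_set_collection`.
#' @export
collection_category <- function(collection) attr(collection, "category")

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, `name <TAB> description <TAB> gene1 <TAB> gene2 ...`
#'
#' @param path file path.
#' @param category category tag to attach (see [gene_set_collection()]).
#' @rdname gmt_io
#' @export
read_gmt <- function(path, category = "GO") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  gene_set_collection(sets, category = category)
}

#' @param collection collection to write (descriptions are set to the
#'   category tag).
#' @rdname gmt_io
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, collection_category(collection), collection[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric enrichment of a gene set in a community
#'
#' P(X >= k) where X is the intersection size of a random draw of
#' `|community|` genes from the universe against the `|geneset|` successes.
#'
#' @param community character vector of community gene ids.
#' @param geneset character vector of gene-set ids.
#' @param universe character vector of all genes under study (the
#'   multi-network node set); community and geneset must be subsets.
#' @return list with `p` (raw p-value), `intersection` (gene ids),
#'   `community_size`, `set_size`, `universe_size`.
#' @export
hypergeom_enrichment <- function(community, geneset, universe) {
  community <- unique(community)
  geneset <- unique(geneset)
  universe <- unique(universe)
  if (length(community) == 0 || length(geneset) == 0)
    stop("community and gene set must be nonempty")
  if (!all(community %in% universe) || !all(geneset %in% universe))
    stop("community and gene set must be subsets of the universe")
  inter <- intersect(community, geneset)
  k <- length(inter)
  p <- stats::phyper(k - 1, length(geneset),
                     length(universe) - length(geneset),
                     length(community), lower.tail = FALSE)
  list(p = p, intersection = inter, community_size = length(community),
       set_size = length(geneset), universe_size = length(universe))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control (wraps
#' [stats::p.adjust()] after validating the inputs).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment of every (community, gene set) pair
#'
#' Runs [hypergeom_enrichment()] for all pairs and adjusts the whole family
#' jointly with Benjamini-Hochberg.
#'
#' @param partition a `partition`.
#' @param collections a `gene_set_collection` or list of collections.
#' @param universe gene universe; default the partition's nodes.
#' @param min_size smallest community tested (default 2; singletons carry no
#'   co-membership signal).
#' @return data frame with columns community, set, category, intersection,
#'   community_size, set_size, universe_size, p_raw, p_adjust, genes
#'   (comma-separated intersection).
#' @export
enrich_partition <- function(partition, collections,
                             universe = names(partition), min_size = 2) {
  if (inherits(collections, "gene_set_collection"))
    collections <- list(collections)
  if (length(collections) == 0) stop("no gene-set collections supplied")
  comms <- partition_to_sets(partition)
  comms <- comms[vapply(comms, length, 0L) >= min_size]
  rows <- list()
  for (coll in collections) {
    cat_tag <- collection_category(coll)
    for (set_name in names(coll)) {
      gs <- intersect(coll[[set_name]], universe)
      if (length(gs) == 0) next
      for (cid in names(comms)) {
        res <- hypergeom_enrichment(comms[[cid]], gs, universe)
        rows[[length(rows) + 1]] <- data.frame(
          community = cid, set = set_name, category = cat_tag,
          intersection = length(res$intersection),
          community_size = res$community_size, set_size = res$set_size,
          universe_size = res$universe_size, p_raw = res$p,
          genes = paste(sort(res$intersection), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) stop("no testable (community, set) pairs")
  out <- do.call(rbind, rows)
  out$p_adjust <- bh_adjust(out$p_raw)
  out[, c("community", "set", "category", "intersection", "community_size",
          "set_size", "universe_size", "p_raw", "p_adjust", "genes")]
}

#' Fraction of functionally homogeneous communities
#'
#' A community is functionally homogeneous when at least one gene set is
#' enriched in it at BH-adjusted p below `fdr`.  This is the headline
#' comparison statistic between the multi-network and the single
#' co-expression layer.
#'
#' @inheritParams enrich_partition
#' @param fdr BH-adjusted significance threshold (default 0.05).
#' @return list with `fraction`, `flags` (named logical per community) and
#'   `table` (the full enrichment table).
#' @export
functional_homogeneity <- function(partition, collections,
                                   universe = names(partition), fdr = 0.05,
                                   min_size = 2) {
  tab <- enrich_partition(partition, collections, universe, min_size)
  comms <- names(partition_to_sets(partition))
  sig <- tapply(tab$p_adjust < fdr, tab$community, any)
  flags <- stats::setNames(rep(FALSE, length(comms)), comms)
  flags[names(sig)] <- as.logical(sig)
  list(fraction = mean(flags), flags = flags, table = tab)
}

#' Signature-intersection report
#'
#' Tests every (signature, community) pair by the hypergeometric upper tail
#' and adjusts the whole family with Benjamini-Hochberg, reporting the rows
#' in a signature-class / community / p-value / sizes / gene-list layout.
#'
#' @param partition a `partition`.
#' @param signatures a `gene_set_collection` tagged `signature`.
#' @param universe gene universe (default the partition's nodes).
#' @param min_size smallest community tested.
#' @return data frame with columns class, communityID, p_value (BH
#'   adjusted), p_raw, signaturesize, communitysize, intersection, genes;
#'   ordered by p_value.
#' @export
signature_intersection <- function(partition, signatures,
                                   universe = names(partition),
                                   min_size = 2) {
  if (!inherits(signatures, "gene_set_collection") ||
      collection_category(signatures) != "signature")
    stop("signatures must be a gene_set_collection tagged 'signature'")
  tab <- enrich_partition(partition, signatures, universe, min_size)
  out <- data.frame(class = tab$set, communityID = tab$community,
                    p_value = tab$p_adjust, p_raw = tab$p_raw,
                    signaturesize = tab$set_size,
                    communitysize = tab$community_size,
                    intersection = tab$intersection, genes = tab$genes,
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$p_raw), , drop = FALSE]
}
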