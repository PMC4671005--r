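#' Tumor-specific enriched categories not visible from expression alone
#'
#' Pure set algebra on four enrichment tables (tumor/normal multi-network,
#' tumor/normal expression network): a category is *tumor specific* for a
#' network when it is significant somewhere in the tumor communities but
#' nowhere in the normal ones; the multi-network's added value is what
#' remains after also subtracting the expression network's tumor-specific
#' categories:
#' \deqn{(sig(TM) \setminus sig(NM)) \setminus
#'       (sig(TE) \setminus sig(NE)).}
#' The result is split by category tag, and an export of reciprocal
#' p-values (radar-plot style) is produced for the categories whose best
#' raw enrichment p-value is below `radar_p`.
#'
#' @param tm,nm,te,ne enrichment tables as produced by [enrich_partition()]
#'   (columns `set`, `category`, `p_raw`, `p_adjust`) for the tumor
#'   multi-network, normal multi-network, tumor expression network and
#'   normal expression network.
#' @param threshold BH-adjusted significance threshold defining
#'   "significant" (default 0.05).
#' @param radar_p raw-p cutoff for the radar export (default 1e-5).
#' @return list with `categories` (data frame `set`, `category`),
#'   `by_category` (list of set names split by tag) and `radar` (data frame
#'   `set`, `category`, `p`, `reciprocal_p`).
#' @export
tumor_specific_categories <- function(tm, nm, te, ne, threshold = 0.05,
                                      radar_p = 1e-5) {
  tabs <- list(tm = tm, nm = nm, te = te, ne = ne)
  catmap <- .category_map(tabs)
  sig <- lapply(tabs, .significant_sets, threshold = threshold)
  s_multi <- setdiff(sig$tm, sig$nm)
  s_expr <- setdiff(sig$te, sig$ne)
  keep <- setdiff(s_multi, s_expr)
  categories <- data.frame(set = keep,
                           category = unname(catmap[keep]),
                           stringsAsFactors = FALSE)
  categories <- categories[order(categories$category, categories$set), ,
                           drop = FALSE]
  rownames(categories) <- NULL
  by_category <- split(categories$set, categories$category)
  best_p <- tapply(tm$p_raw, tm$set, min)
  radar <- categories
  radar$p <- unname(best_p[radar$set])
  radar <- radar[!is.na(radar$p) & radar$p < radar_p, , drop = FALSE]
  radar$reciprocal_p <- 1 / radar$p
  rownames(radar) <- NULL
  list(categories = categories, by_category = by_category, radar = radar)
}

.significant_sets <- function(tab, threshold) {
  unique(tab$set[tab$p_adjust < threshold])
}

.category_map <- function(tabs) {
  all <- do.call(rbind, lapply(tabs, function(t)
    unique(t[, c("set", "category"), drop = FALSE])))
  all <- unique(all)
  dup <- all$set[duplicated(all$set)]
  if (length(dup) > 0)
    stop("inconsistent category tags across inputs for set(s): ",
         paste(unique(dup), collapse = ", "))
  stats::setNames(all$category, all$set)
}
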