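#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with its default.  A
#' YAML file with the same keys can be loaded with [read_pipeline_config()];
#' unknown keys are rejected so typos fail loudly.
#'
#' @param expression path to the expression matrix (required).
#' @param conditions path to the sample-condition sidecar (required for
#'   differential expression; optional otherwise).
#' @param tf_targets,mirna_targets,ppi,gold optional input paths (TF table,
#'   miRNA table with sources, PPI edge list, gold-standard edge list).
#' @param gene_sets optional named character vector of GMT paths; names are
#'   category tags (see [gene_set_collection()]).
#' @param signatures optional GMT path of signature sets.
#' @param mi_bins bins for the MI estimator (default
#'   `ceiling(sqrt(n_samples))`).
#' @param alpha_grid disparity-filter significance grid within
#'   `[0.01, 0.5]`.
#' @param alpha fixed significance level; `NULL` selects per layer via
#'   [select_alpha()] (requires `gold`).
#' @param coexpression_condition which samples feed the co-expression layer:
#'   `tumor` (default), `normal` or `all`.
#' @param algorithm,n_runs,tau consensus detection configuration (defaults
#'   `louvain`, 100 runs, tau 0.5).
#' @param seed master seed (default 42).
#' @param fdr BH threshold for enrichment/homogeneity (default 0.05).
#' @param radar_p raw-p cutoff for the radar export (default 1e-5).
#' @param fisher_sig,balance_fold alpha-selection thresholds.
#' @param log2_offset offset passed to [log2_transform()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, conditions = NULL,
                            tf_targets = NULL, mirna_targets = NULL,
                            ppi = NULL, gold = NULL, gene_sets = NULL,
                            signatures = NULL, mi_bins = NULL,
                            alpha_grid = c(0.01, 0.05, 0.1, 0.25, 0.5),
                            alpha = NULL,
                            coexpression_condition = "tumor",
                            algorithm = "louvain", n_runs = 100, tau = 0.5,
                            seed = 42, fdr = 0.05, radar_p = 1e-5,
                            fisher_sig = 0.05, balance_fold = 10,
                            log2_offset = 0) {
  if (missing(expression) || is.null(expression))
    stop("missing required input layer: expression")
  if (n_runs < 2) stop("n_runs must be >= 2")
  for (th in c(tau, fdr, radar_p, fisher_sig))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  structure(list(
    expression = expression, conditions = conditions,
    tf_targets = tf_targets, mirna_targets = mirna_targets, ppi = ppi,
    gold = gold, gene_sets = gene_sets, signatures = signatures,
    mi_bins = mi_bins, alpha_grid = alpha_grid, alpha = alpha,
    coexpression_condition = coexpression_condition,
    algorithm = algorithm, n_runs = n_runs, tau = tau, seed = seed,
    fdr = fdr, radar_p = radar_p, fisher_sig = fisher_sig,
    balance_fold = balance_fold, log2_offset = log2_offset),
    class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML key/value file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the complete multi-network pipeline
#'
#' Preprocess the expression matrix, build and intersect the layers, select
#' alpha and filter, detect per-layer and cross-layer consensus communities,
#' then score the final partition (enrichment, differential expression,
#' signatures -- each only when its inputs are configured).  Every output is
#' written under `out_dir` and a machine-readable `manifest.json` records
#' the package version, seed, resolved configuration, per-layer alpha
#' values, per-stage node/edge counts and MD5 checksums of all files, so two
#' runs with the same inputs and seed are byte-identical.
#'
#' @param config a `pipeline_config`.
#' @param out_dir run directory (created; existing files overwritten).
#' @return invisibly, a list with the partition, layer partitions, filter
#'   reports and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("layers", "filter", "communities", "scoring"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  log_counts <- list()

  expr <- .stage("preprocess", {
    raw <- read_expression_matrix(config$expression)
    preprocess_expression(raw, offset = config$log2_offset)
  })
  condition <- NULL
  if (!is.null(config$conditions))
    condition <- .stage("preprocess", read_sample_conditions(config$conditions))
  write_expression_matrix(expr, file.path(out_dir, "preprocessed.tsv"))

  layers <- .stage("layers", {
    emat <- expr
    if (config$coexpression_condition != "all") {
      if (is.null(condition))
        stop("coexpression_condition='", config$coexpression_condition,
             "' requires a conditions file")
      emat <- expr[, names(condition)[condition ==
                                        config$coexpression_condition],
                   drop = FALSE]
    }
    bins <- config$mi_bins %||% ceiling(sqrt(ncol(emat)))
    out <- list(expression = build_expression_layer(emat, bins = bins))
    if (!is.null(config$tf_targets))
      out$tf <- co_targeting_projection(
        read_regulator_targets(config$tf_targets), name = "tf")
    if (!is.null(config$mirna_targets))
      out$mirna <- co_targeting_projection(
        mirna_consensus_filter(read_regulator_targets(config$mirna_targets)),
        name = "mirna")
    if (!is.null(config$ppi)) {
      ppi <- read_edge_list(config$ppi)
      out$ppi <- weighted_layer(
        data.frame(from = ppi$gene1, to = ppi$gene2, weight = 1), name = "ppi")
    }
    out
  })

  multinet <- if (length(layers) >= 2) {
    .stage("layers", intersect_to_multinetwork(unname(layers)))
  } else {
    structure(layers, class = "multinet")
  }
  for (nm in names(multinet)) {
    write_layer(multinet[[nm]], file.path(out_dir, "layers",
                                          paste0(nm, ".tsv")))
    log_counts[[paste0("layer_", nm)]] <-
      c(nodes = igraph::vcount(multinet[[nm]]),
        edges = igraph::ecount(multinet[[nm]]))
  }

  filter_layers <- setdiff(names(multinet), "ppi")
  alphas <- .stage("filter", {
    if (!is.null(config[["alpha"]])) {
      stats::setNames(rep_len(config[["alpha"]], length(filter_layers)),
                      filter_layers)
    } else {
      if (is.null(config[["gold"]]))
        stop("automatic alpha selection requires a gold-standard edge list")
      gold <- read_edge_list(config[["gold"]])
      sel <- lapply(filter_layers, function(nm) {
        s <- select_alpha(multinet[[nm]], gold, alphas = config$alpha_grid,
                          fisher_sig = config$fisher_sig)
        rep <- s$report
        rep$layer <- nm
        utils::write.table(rep, file.path(out_dir, "filter",
                                          paste0("report_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        s$recommended
      })
      a <- stats::setNames(unlist(sel), filter_layers)
      if (any(is.na(a)))
        stop("no admissible alpha for layer(s): ",
             paste(filter_layers[is.na(a)], collapse = ", "))
      a
    }
  })

  detection <- .stage("communities", detect_multinetwork_communities(
    multinet, alpha = alphas, filter_layers = filter_layers,
    algorithm = config$algorithm, n_runs = config$n_runs, tau = config$tau,
    seed = config$seed))
  for (nm in names(detection$filtered)) {
    write_layer(detection$filtered[[nm]],
                file.path(out_dir, "filter", paste0(nm, "_filtered.tsv")))
    log_counts[[paste0("filtered_", nm)]] <-
      c(nodes = igraph::vcount(detection$filtered[[nm]]),
        edges = igraph::ecount(detection$filtered[[nm]]))
  }
  balance <- balance_check(
    vapply(detection$filtered, igraph::ecount, 0),
    fold_factor = config$balance_fold)
  for (nm in names(detection$layer_partitions))
    write_partition(detection$layer_partitions[[nm]],
                    file.path(out_dir, "communities",
                              paste0("partition_", nm, ".tsv")))
  write_partition(detection$partition,
                  file.path(out_dir, "communities", "partition_multinet.tsv"))
  write_consensus_matrix(attr(detection$partition, "cross_layer_matrix"),
                         file.path(out_dir, "communities",
                                   "cross_layer_consensus.tsv"))

  comparison <- .stage("compare", {
    df <- data.frame(
      layer = names(detection$layer_partitions),
      nmi_vs_multinet = vapply(detection$layer_partitions, nmi, 0,
                               b = detection$partition),
      n_communities = vapply(detection$layer_partitions, n_communities, 0L))
    df <- rbind(df, data.frame(layer = "multinet", nmi_vs_multinet = 1,
                               n_communities = n_communities(
                                 detection$partition)))
    utils::write.table(df, file.path(out_dir, "comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    df
  })

  scoring <- .stage("scoring", {
    out <- list()
    universe <- names(detection$partition)
    if (!is.null(config$gene_sets)) {
      colls <- lapply(seq_along(config$gene_sets), function(i)
        read_gmt(config$gene_sets[[i]],
                 category = names(config$gene_sets)[i]))
      hom <- functional_homogeneity(detection$partition, colls,
                                    universe = universe, fdr = config$fdr)
      utils::write.table(hom$table,
                         file.path(out_dir, "scoring", "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$homogeneity_fraction <- hom$fraction
    }
    if (!is.null(condition) &&
        all(c("tumor", "normal") %in% condition[colnames(expr)])) {
      de <- partition_diff_expression(detection$partition,
                                      expr[universe, , drop = FALSE],
                                      condition)
      utils::write.table(de, file.path(out_dir, "scoring", "diffexp.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$diffexp <- de
    }
    if (!is.null(config$signatures)) {
      sigs <- read_gmt(config$signatures, category = "signature")
      st <- signature_intersection(detection$partition, sigs,
                                   universe = universe)
      utils::write.table(st, file.path(out_dir, "scoring", "signatures.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$signatures <- st
    }
    out
  })

  manifest <- list(
    package = "genemux",
    version = as.character(utils::packageVersion("genemux")),
    seed = config$seed,
    config = config[setdiff(names(config), NULL)],
    alpha = as.list(alphas),
    balance = balance,
    counts = log_counts,
    n_communities = n_communities(detection$partition),
    checksums = .dir_checksums(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(partition = detection$partition,
                 layer_partitions = detection$layer_partitions,
                 filtered = detection$filtered, alphas = alphas,
                 comparison = comparison, scoring = scoring,
                 manifest = manifest))
}

.dir_checksums <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(dir, files))
  as.list(stats::setNames(unname(sums), files))
}
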