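# Configuration-driven pipeline: simulate/ingest -> build graphs -> train ->
# evaluate -> analyze, with a manifest for reproducibility, plus the
# ablation matrix used to compare architectural variants.

.cfg_from_list <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  do.call(model_config, lst)
}

#' Serialize the built graphs to plain-text files
#'
#' Each view graph becomes an edge-list TSV (`src`, `dst`, `weight`), the
#' target adjacency a MatrixMarket file, and the gene map a TSV
#' (`cell`, `rank`, `gene`).
#'
#' @param graphs named list of `view_graph`s.
#' @param target a `target_adjacency` (optional).
#' @param gene_graph a [gene_block_graph()] (optional).
#' @param ds the [spatial_dataset()] (for gene names in the gene map).
#' @param dir output directory.
#' @return Invisibly, the vector of written paths.
#' @export
write_graphs <- function(graphs, target = NULL, gene_graph = NULL,
                         ds = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in names(graphs)) {
    tr <- Matrix::summary(methods::as(graphs[[v]]$A, "TsparseMatrix"))
    w <- graphs[[v]]$W[cbind(tr$i, tr$j)]
    p <- file.path(dir, paste0("graph_", v, ".tsv"))
    utils::write.table(data.frame(src = tr$i, dst = tr$j, weight = w),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(target)) {
    p <- file.path(dir, "target_adjacency.mtx")
    Matrix::writeMM(target$A, p)
    paths <- c(paths, p)
  }
  if (!is.null(gene_graph)) {
    p <- file.path(dir, "gene_map.tsv")
    gm <- do.call(rbind, lapply(seq_along(gene_graph$gene_map), function(i) {
      gi <- gene_graph$gene_map[[i]]
      data.frame(cell = i, rank = seq_along(gi),
                 gene = if (is.null(ds)) gi else ds$gene_names[gi])
    }))
    utils::write.table(gm, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.manifest <- function(config, input_paths, seed) {
  list(config = config,
       seed = seed,
       inputs = if (length(input_paths)) {
         as.list(tools::md5sum(unlist(input_paths)))
       } else list(),
       package_version = as.character(utils::packageVersion("ccinet")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate/ingest, graph construction, training, evaluation, and
#' network analysis as configured, writing every artifact (manifest,
#' graphs, training history, metrics, predicted edges, analysis reports)
#' under one run directory. The manifest — config snapshot, seed, input
#' file digests, package version — is written before training begins.
#'
#' @param config a YAML file path or an equivalent nested list with
#'   sections `data` (either `simulate:` parameters for
#'   [simulation_spec()] or `files:` with `expr`, `coords`, `format`,
#'   `lr_pairs`), `model` (arguments of [model_config()]), `split`
#'   (`r`, `val_fraction`), and `analysis` (`top_fraction`,
#'   `hub_degree`).
#' @param out_dir run directory (created).
#' @return Invisibly, a list with the trained model, metrics, network,
#'   and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (sec in c("data")) {
    if (is.null(config[[sec]])) stop("config is missing section: ", sec)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- .cfg_from_list(config$model %||% list())

  input_paths <- character(0)
  if (!is.null(config$data$simulate)) {
    spec <- do.call(simulation_spec, config$data$simulate %||% list())
    sim <- simulate_dataset(spec)
    ds <- sim$dataset
    db <- make_toy_lr_db(spec)
  } else if (!is.null(config$data$files)) {
    f <- config$data$files
    for (key in c("expr", "coords", "lr_pairs")) {
      if (is.null(f[[key]])) stop("config data.files is missing: ", key)
      if (!file.exists(f[[key]])) {
        stop("input file not found (data.files.", key, "): ", f[[key]])
      }
    }
    ds <- read_dataset(f$expr, f$coords, format = f$format %||% "csv",
                       labels_path = f$labels)
    db <- read_lr_db(f$lr_pairs)
    input_paths <- unlist(f[c("expr", "coords", "lr_pairs")])
  } else {
    stop("config data must have either 'simulate' or 'files'")
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(.manifest(config, input_paths, cfg$seed),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE)

  graphs <- list(spatial = build_spatial_graph(ds, cfg),
                 lr = build_lr_graph(ds, db, cfg),
                 similarity = build_similarity_graph(ds, cfg))
  gene_graph <- if (.gene_enabled(cfg)) build_gene_graph(ds, db, cfg)
                else NULL
  target <- build_target(graphs, cfg)
  write_graphs(graphs, target, gene_graph, ds,
               dir = file.path(out_dir, "graphs"))

  sp <- config$split %||% list()
  split <- split_edges(target, r = sp$r %||% 0.3,
                       val_fraction = sp$val_fraction %||% 0.05,
                       seed = cfg$seed)
  fit <- train_model(ds, graphs, gene_graph, target, cfg, split)
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  Z <- model_embed(fit$params, fit$inputs, cfg)
  metrics <- evaluate_reconstruction(Z, split)
  jsonlite::write_json(unclass(metrics), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  an <- config$analysis %||% list()
  A_hat <- decode_adjacency(Z)
  net <- threshold_top_edges(A_hat, an$top_fraction %||% 0.05,
                             coords = ds$coords, labels = ds$labels)
  utils::write.table(net$edges, file.path(out_dir, "predicted_edges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stats_tab <- topology_stats(net)
  utils::write.csv(stats_tab, file.path(out_dir, "topology.csv"),
                   row.names = FALSE)
  hubs <- find_hubs(net, an$hub_degree %||% 10L)
  ks <- NULL
  if (!is.null(ds$labels)) {
    ks <- tryCatch(intra_inter_distance_test(net), error = function(e) e)
    report <- if (inherits(ks, "error")) {
      list(error = conditionMessage(ks))
    } else {
      list(statistic = ks$statistic, p_value = ks$p_value,
           n_intra = length(ks$intra), n_inter = length(ks$inter))
    }
    jsonlite::write_json(report, file.path(out_dir, "ks_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (inherits(ks, "error")) ks <- NULL
  }

  invisible(list(dataset = ds, fit = fit, metrics = metrics, network = net,
                 hubs = hubs, ks = ks, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Graph-subset variants toggle the cell-level views only; the gene-level
# block graph and its attention branch are architectural components kept in
# every variant (the modalities compared are spatial proximity,
# ligand-receptor signaling, and transcriptional similarity).
.ablation_variants <- list(
  full = identity,
  no_attention = function(cfg) { cfg$use_attention <- FALSE; cfg },
  no_contrast = function(cfg) { cfg$use_contrast <- FALSE; cfg },
  no_align = function(cfg) { cfg$use_align <- FALSE; cfg },
  spatial_only = function(cfg) {
    cfg$views_enabled <- c("spatial", "gene"); cfg },
  spatial_lr = function(cfg) {
    cfg$views_enabled <- c("spatial", "lr", "gene"); cfg },
  spatial_sim = function(cfg) {
    cfg$views_enabled <- c("spatial", "similarity", "gene"); cfg },
  lr_sim = function(cfg) {
    cfg$views_enabled <- c("lr", "similarity", "gene"); cfg },
  all_views = identity)

#' Compare architectural and graph-subset ablations
#'
#' Runs each named variant over the same seeds and edge splits (the
#' supervision target is shared, so per-seed splits are identical across
#' variants) and tabulates the mean and sd of the test metrics. Available
#' variants: `full`, `no_attention`, `no_contrast`, `no_align`,
#' `spatial_only`, `spatial_lr`, `spatial_sim`, `lr_sim`, `all_views`
#' (graph-subset variants keep the gene-level block graph and toggle the
#' cell-level views).
#'
#' @param ds a [spatial_dataset()].
#' @param db an [lr_db()].
#' @param cfg the base [model_config()].
#' @param variants character vector of variant names.
#' @param seeds integer seeds shared across variants.
#' @param r held-out test fraction.
#' @return List with `table` (one row per variant: mean/sd AP, AUROC,
#'   AUPRC, F1) and `per_seed` (all per-seed rows).
#' @export
ablation_matrix <- function(ds, db, cfg = model_config(),
                            variants = c("full", "no_attention",
                                         "no_contrast", "no_align"),
                            seeds = 1:3, r = 0.3) {
  unknown <- setdiff(variants, names(.ablation_variants))
  if (length(unknown)) stop("unknown variant(s): ",
                            paste(unknown, collapse = ", "))
  graphs <- list(spatial = build_spatial_graph(ds, cfg),
                 lr = build_lr_graph(ds, db, cfg),
                 similarity = build_similarity_graph(ds, cfg))
  gene_graph <- build_gene_graph(ds, db, cfg)
  target <- build_target(graphs, cfg)
  splits <- lapply(seeds, function(s) split_edges(target, r = r, seed = s))
  rows <- list()
  for (vn in variants) {
    cfg_v <- .ablation_variants[[vn]](cfg)
    for (k in seq_along(seeds)) {
      cfg_s <- cfg_v
      cfg_s$seed <- as.integer(seeds[k])
      gg <- if (.gene_enabled(cfg_s)) gene_graph else NULL
      fit <- train_model(ds, graphs, gg, target, cfg_s, splits[[k]])
      Z <- model_embed(fit$params, fit$inputs, cfg_s)
      m <- evaluate_reconstruction(Z, splits[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, seed = seeds[k], ap = m$ap, auroc = m$auroc,
        auprc = m$auprc, f1 = m$f1)
    }
  }
  per_seed <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(unique(per_seed$variant), function(vn) {
    sub <- per_seed[per_seed$variant == vn, ]
    data.frame(variant = vn,
               ap_mean = mean(sub$ap), ap_sd = stats::sd(sub$ap),
               auroc_mean = mean(sub$auroc), auroc_sd = stats::sd(sub$auroc),
               auprc_mean = mean(sub$auprc), f1_mean = mean(sub$f1))
  }))
  list(table = tab, per_seed = per_seed)
}
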