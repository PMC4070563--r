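## End-to-end pipeline: simulate -> encode -> network (linear or MI)
## -> topology -> modules, with a JSON manifest and full seeded
## reproducibility.  The command-line wrapper in inst/cli is a thin
## layer over these functions.

#' Validated pipeline configuration
#'
#' All numeric fields are checked against the preconditions of the
#' operations that consume them before any work starts.
#'
#' @param out_dir run directory for TSV outputs and the manifest.
#' @param seed integer RNG seed driving every stage.
#' @param n_genes,n_conditions synthetic matrix shape.
#' @param module_sizes planted module sizes.
#' @param flip_prob per-cell corruption probability (< 0.5).
#' @param method network construction: \code{"threshold"},
#'   \code{"mknn"} or \code{"mi"}.
#' @param pcc_threshold PCC cutoff in (0, 1] (default 0.9).
#' @param k mKNN neighbourhood size.
#' @param mi_algo MI post-processing: \code{"aracne_m"},
#'   \code{"aracne_a"}, \code{"clr"}, \code{"mrnet"}, \code{"none"}.
#' @param fraction max-fraction threshold in (0, 1] (default 0.8).
#' @param cluster_algo \code{"fagec"} or \code{"mcl"}.
#' @param lambda FAG-EC locking strictness (> 0).
#' @param inflation MCL inflation (> 1).
#' @param min_size minimum module size (default 6).
#' @param hub_min_degree,top_n topology cutoffs (defaults 50, 90).
#' @return list with class \code{"RunConfig"}.
#' @export
runConfig <- function(out_dir, seed = 1L, n_genes = 200L,
                      n_conditions = 100L, module_sizes = c(25L, 25L, 25L, 25L),
                      flip_prob = 0.1, method = c("mknn", "threshold", "mi"),
                      pcc_threshold = 0.9, k = 10L,
                      mi_algo = c("aracne_m", "aracne_a", "clr", "mrnet", "none"),
                      fraction = 0.8, cluster_algo = c("fagec", "mcl"),
                      lambda = 1, inflation = 2, min_size = 6L,
                      hub_min_degree = 50L, top_n = 90L) {
  method <- match.arg(method)
  mi_algo <- match.arg(mi_algo)
  cluster_algo <- match.arg(cluster_algo)
  stopifnot(is.numeric(seed), length(seed) == 1,
            n_genes >= sum(module_sizes), n_conditions >= 3,
            all(module_sizes >= 1))
  if (flip_prob >= 0.5) stop("flip_prob must be < 0.5")
  if (pcc_threshold <= 0 || pcc_threshold > 1)
    stop("pcc_threshold must lie in (0, 1]")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (k < 1 || k >= n_genes) stop("k must satisfy 1 <= k < n_genes")
  if (lambda <= 0) stop("lambda must be > 0")
  if (inflation <= 1) stop("inflation must be > 1")
  if (min_size < 1) stop("min_size must be >= 1")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_genes = as.integer(n_genes),
                 n_conditions = as.integer(n_conditions),
                 module_sizes = as.integer(module_sizes),
                 flip_prob = flip_prob, method = method,
                 pcc_threshold = pcc_threshold, k = as.integer(k),
                 mi_algo = mi_algo, fraction = fraction,
                 cluster_algo = cluster_algo, lambda = lambda,
                 inflation = inflation, min_size = as.integer(min_size),
                 hub_min_degree = as.integer(hub_min_degree),
                 top_n = as.integer(top_n)),
            class = "RunConfig")
}

.writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Simulates a planted-module ternary matrix, infers the configured
#' network, writes the topology battery, detects modules, and records a
#' JSON manifest of parameters, seeds and per-stage row counts.
#' Identical config and seed give byte-identical outputs.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- plantedExpressionTruth(cfg$module_sizes, cfg$n_conditions,
                                  flip_prob = cfg$flip_prob,
                                  seed = cfg$seed)
  tem <- synthExpression(cfg$n_genes, cfg$n_conditions, truth,
                         seed = cfg$seed + 1L)
  v <- ternaryValues(tem)
  .writeTsv(data.frame(gene_id = rownames(v), v, check.names = FALSE),
            file.path(cfg$out_dir, "expression.tsv"))

  s <- pearsonAll(tem)
  net <- switch(cfg$method,
    threshold = pccThresholdNetwork(s, cfg$pcc_threshold),
    mknn = mknnNetwork(s, cfg$k),
    mi = {
      mi <- kraskovMiAll(tem, miConfig(seed = cfg$seed + 2L))
      w <- switch(cfg$mi_algo,
        aracne_m = aracnePrune(mi, "multiplicative"),
        aracne_a = aracnePrune(mi, "additive"),
        clr = clrTransform(mi),
        mrnet = mrnetBuild(mi),
        none = mi)
      fractionThresholdNetwork(w, cfg$fraction)
    })
  writeNetwork(net, file.path(cfg$out_dir, "network.tsv"))

  rep <- topologyReport(net, cfg$hub_min_degree, cfg$top_n, cfg$min_size)
  .writeTsv(rep$per_node, file.path(cfg$out_dir, "topology_per_node.tsv"))
  .writeTsv(rep$degree_distribution,
            file.path(cfg$out_dir, "degree_distribution.tsv"))
  .writeTsv(rep$path_distribution,
            file.path(cfg$out_dir, "path_distribution.tsv"))

  ms <- switch(cfg$cluster_algo,
    fagec = fagecCluster(net, cfg$lambda, cfg$min_size),
    mcl = mclCluster(net, cfg$inflation, min_size = cfg$min_size))
  mods <- moduleList(ms)
  mod_tab <- if (length(mods))
    data.frame(module_id = rep(names(mods), lengths(mods)),
               gene_id = unlist(mods, use.names = FALSE))
  else data.frame(module_id = character(0), gene_id = character(0))
  .writeTsv(mod_tab, file.path(cfg$out_dir, "modules.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ternet")),
    parameters = unclass(cfg),
    stages = list(
      expression = list(rows = nrow(v), cols = ncol(v)),
      network = list(nodes = nNodes(net), edges = nEdges(net)),
      topology = list(per_node_rows = nrow(rep$per_node)),
      modules = list(n_modules = length(mods),
                     sizes = as.integer(lengths(mods)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
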