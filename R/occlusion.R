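# Half-edge occlusion experiments
#
# For each a-priori network and encoding (inner / connecting edges),
# paired sets of members are trained on half of the 6670 unique edges:
# the include arm's halves always contain the network's edge set, the
# exclude arm's halves never do, with the remaining slots filled by a
# fresh random draw of non-network edges per member. Comparing the two
# arms' test AUROC distributions (Mann-Whitney U, Holm-corrected across
# the report) measures the network's contribution to classification,
# overall and within the rest/task strata.

#' Occlusion design for one network and edge mode
#'
#' @param network a [network_definition()].
#' @param edge_mode `"inner"` or `"connecting"`.
#' @param k members per arm.
#' @return object of class `occlusion_design` (network, mode, its edge
#'   set, the half size `floor(E/2)`).
#' @export
occlusion_design <- function(network, edge_mode = c("inner", "connecting"),
                             k = 300L) {
  edge_mode <- match.arg(edge_mode)
  set <- if (edge_mode == "inner") inner_edges(network)
         else connecting_edges(network)
  E <- n_edges(network$n_nodes)
  half <- floor(E / 2)
  if (length(set) > half)
    stop2("network edge set (", length(set),
          " edges) does not fit in one half (", half, ")")
  structure(list(network = network, edge_mode = edge_mode,
                 edge_set = set, k = as.integer(k),
                 n_edges = E, half = as.integer(half)),
            class = "occlusion_design")
}

#' Per-member include/exclude edge masks
#'
#' Include masks are the network's edge set plus a fresh random fill of
#' non-network edges up to half of all edges; exclude masks are a fresh
#' random half drawn entirely from non-network edges. One independent
#' draw per member. (With an odd total edge count the leftover edge is
#' simply never forced in: each half has `floor(E/2)` slots.)
#'
#' @param design an [occlusion_design()].
#' @param seed draw seed.
#' @return list with `include` and `exclude`: each a list of `k` sorted
#'   0-based edge-id vectors of length `half`.
#' @export
build_masks <- function(design, seed = 1L) {
  stopifnot(inherits(design, "occlusion_design"))
  non_net <- setdiff(0:(design$n_edges - 1L), design$edge_set)
  fill <- design$half - length(design$edge_set)
  with_seed(substream_seed(seed, "masks"), {
    include <- lapply(seq_len(design$k), function(j)
      sort(c(design$edge_set, non_net[sample.int(length(non_net), fill)])))
    exclude <- lapply(seq_len(design$k), function(j)
      sort(non_net[sample.int(length(non_net), design$half)]))
    list(include = include, exclude = exclude)
  })
}

# per-member test AUROCs overall and within strata
.member_arm_aurocs <- function(edge_array, phenotypes, masks, member_cfg,
                               balance_cfg, seed, tag) {
  labels <- as.integer(phenotypes$sex)
  res <- lapply(seq_along(masks), function(j) {
    subjects <- seq_len(nrow(phenotypes))
    if (!is.null(balance_cfg)) {
      cfg_b <- balance_cfg
      cfg_b$seed <- substream_seed(seed, paste0(tag, "-draw"), j)
      bal <- balance(phenotypes, cfg_b, class_col = "sex")
      if (bal$certificate$status != "success")
        stop2("occlusion member ", j, " (", tag, "): subsample draw failed")
      subjects <- which(phenotypes$subject_id %in% bal$retained)
    }
    cfg_m <- member_cfg
    cfg_m$seed <- substream_seed(seed, tag, j)
    m <- train_member(edge_array, labels, cfg_m, subjects = subjects,
                      mask = masks[[j]],
                      subject_ids = phenotypes$subject_id)
    strat <- phenotypes$condition[m$test_idx]
    strat_auc <- function(keep) {
      if (length(unique(m$test_labels[keep])) < 2L) return(NA_real_)
      auroc(m$test_probs[keep, 2], m$test_labels[keep])
    }
    list(member = m, all = m$test_auroc,
         rest = strat_auc(strat == "rest"), task = strat_auc(strat == "task"))
  })
  res
}

#' Run the occlusion experiment grid
#'
#' Trains `2 x k` members (include and exclude arms) for every
#' network x mode cell on half-edge masked inputs, compares the arms'
#' AUROC distributions per stratum with a two-sided Mann-Whitney U test,
#' and Holm-corrects the p-values across all tests in the report.
#'
#' @param edge_array `n x E x n_bands` edge values.
#' @param phenotypes aligned phenotype table (`subject_id`, `sex`,
#'   `condition`, covariates).
#' @param networks named list of [network_definition()] objects.
#' @param modes subset of `c("inner", "connecting")`.
#' @param k members per arm.
#' @param member_cfg a [member_config()] for the FULL grid; its column
#'   count is adapted to the half grid automatically.
#' @param balance_cfg optional [balance_config()] for per-member
#'   subsample draws.
#' @param strata strata to test (default all/rest/task).
#' @param seed master seed.
#' @param progress print per-cell progress.
#' @return object of class `occlusion_report`: `table` (one row per
#'   network x mode x stratum with arm mean/sd AUROC, U statistic, raw
#'   and Holm-corrected p, direction), `aurocs` (per-cell per-arm member
#'   AUROCs), `ensemble` (per-cell per-arm ensemble AUROC).
#' @export
run_occlusion <- function(edge_array, phenotypes, networks,
                          modes = c("inner", "connecting"), k = 20L,
                          member_cfg = member_config(),
                          balance_cfg = NULL,
                          strata = c("all", "rest", "task"), seed = 1L,
                          progress = FALSE) {
  E <- dim(edge_array)[2]
  V <- as.integer((1 + sqrt(1 + 8 * E)) / 2)
  half <- floor(E / 2)
  cfg_half <- member_cfg
  cfg_half$grid_cols <- as.integer(half / (V - 1L))
  rows <- list()
  aurocs <- list()
  ensembles <- list()
  for (nm in names(networks)) {
    for (mode in modes) {
      design <- occlusion_design(networks[[nm]], mode, k)
      masks <- build_masks(design, seed = substream_seed(seed, paste(nm, mode)))
      cell_seed <- substream_seed(seed, paste("cell", nm, mode))
      arms <- list(
        include = .member_arm_aurocs(edge_array, phenotypes, masks$include,
                                     cfg_half, balance_cfg, cell_seed,
                                     "include"),
        exclude = .member_arm_aurocs(edge_array, phenotypes, masks$exclude,
                                     cfg_half, balance_cfg, cell_seed,
                                     "exclude"))
      for (arm in names(arms)) {
        vals <- arms[[arm]]
        aurocs[[paste(nm, mode, arm, sep = ".")]] <-
          data.frame(network = nm, mode = mode, arm = arm,
                     member = seq_along(vals),
                     all = vapply(vals, `[[`, 0, "all"),
                     rest = vapply(vals, `[[`, 0, "rest"),
                     task = vapply(vals, `[[`, 0, "task"))
        v <- ensemble_votes(lapply(vals, `[[`, "member"), nrow(phenotypes))
        ensembles[[paste(nm, mode, arm, sep = ".")]] <-
          data.frame(network = nm, mode = mode, arm = arm,
                     ensemble_auroc = auroc(v$vote, v$label))
      }
      for (st in strata) {
        inc <- vapply(arms$include, `[[`, 0, st)
        exc <- vapply(arms$exclude, `[[`, 0, st)
        p <- if (k < 2L) NA_real_ else mann_whitney_p(inc, exc)
        rows[[length(rows) + 1L]] <- data.frame(
          network = nm, mode = mode, stratum = st,
          include_mean = mean(inc, na.rm = TRUE),
          include_sd = stats::sd(inc),
          exclude_mean = mean(exc, na.rm = TRUE),
          exclude_sd = stats::sd(exc),
          p_raw = p,
          direction = ifelse(mean(inc, na.rm = TRUE) >=
                               mean(exc, na.rm = TRUE),
                             "include>exclude", "exclude>include"))
      }
      if (progress)
        message(sprintf("occlusion cell %s/%s done (k = %d per arm)", nm,
                        mode, k))
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_holm <- stats::p.adjust(tab$p_raw, method = "holm")
  structure(list(table = tab, aurocs = do.call(rbind, aurocs),
                 ensemble = do.call(rbind, ensembles),
                 k = as.integer(k)),
            class = "occlusion_report")
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat("<occlusion_report>", x$k, "members per arm\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Total training runs of an occlusion grid
#'
#' @param n_modes,n_conditions,n_networks,k design dimensions (edge
#'   modes, include/exclude arms, networks, members per arm).
#' @return the product, e.g. `2 * 2 * 3 * 300 = 3600`.
#' @export
experiment_grid_size <- function(n_modes, n_conditions, n_networks, k) {
  stopifnot(is_count(n_modes), is_count(n_conditions), is_count(n_networks),
            is_count(k))
  as.integer(n_modes * n_conditions * n_networks * k)
}
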