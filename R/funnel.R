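# Docking-ensemble bookkeeping: score-table parsing, two-stage top-model
# selection, the Pnear funnel statistic, and aggregation of per-residue
# energy-decomposition tables.
#
# Pnear summarises how funnel-like a score-vs-RMSD docking plot is:
#
#   Pnear = sum_i exp(-RMSD_i^2 / lambda^2) exp(-E_i / kBT)
#           -----------------------------------------------
#                     sum_j exp(-E_j / kBT)
#
# with lambda the RMSD length scale (1.5 A here) and kBT the energy scale
# (0.62 in the score units of the table). Pnear is 1 when all Boltzmann
# weight sits at RMSD 0 (every low-energy model reproduces the reference
# pose) and 0 when no weight lies near it.

#' Pnear parameters
#'
#' @param lambda RMSD length scale in Angstrom (> 0).
#' @param kBT energy scale in the units of the score column (> 0).
#' @return list of class `ligdyn_pnear_params`.
#' @export
pnear_params <- function(lambda = 1.5, kBT = 0.62) {
  stopifnot(lambda > 0, kBT > 0)
  structure(list(lambda = lambda, kBT = kBT), class = "ligdyn_pnear_params")
}

#' Construct a docking funnel ensemble
#'
#' @param model_ids unique model identifiers.
#' @param total_score per-model total energy (score units, lower = better).
#' @param interface_score per-model binding energy (the Rosetta-style
#'   `interface_delta_X`: bound-state total minus unbound-state total).
#' @param ligand_rmsd per-model unsuperimposed ligand RMSD to the
#'   reference pose (Angstrom, >= 0).
#' @return object of class `ligdyn_funnel`.
#' @export
funnel_ensemble <- function(model_ids, total_score, interface_score, ligand_rmsd) {
  n <- length(model_ids)
  if (n < 1) stop("empty ensemble")
  if (anyDuplicated(model_ids)) stop("model_ids must be unique")
  stopifnot(length(total_score) == n, length(interface_score) == n,
            length(ligand_rmsd) == n)
  if (any(!is.finite(total_score)) || any(!is.finite(interface_score)) ||
      any(!is.finite(ligand_rmsd)))
    stop("non-finite scores or RMSD values")
  if (any(ligand_rmsd < 0)) stop("ligand_rmsd must be >= 0")
  structure(list(model_ids = as.character(model_ids),
                 total_score = as.numeric(total_score),
                 interface_score = as.numeric(interface_score),
                 ligand_rmsd = as.numeric(ligand_rmsd)),
            class = "ligdyn_funnel")
}

#' @export
print.ligdyn_funnel <- function(x, ...) {
  cat("ligdyn funnel ensemble:", length(x$model_ids), "models; ",
      sprintf("interface score range [%.2f, %.2f], rmsd range [%.2f, %.2f] A\n",
              min(x$interface_score), max(x$interface_score),
              min(x$ligand_rmsd), max(x$ligand_rmsd)))
  invisible(x)
}

#' @export
length.ligdyn_funnel <- function(x) length(x$model_ids)

#' Read a docking score table into a funnel ensemble
#'
#' Accepts comma- or whitespace-delimited text with a header. Rosetta-style
#' scorefiles whose rows begin with a `SCORE:` token are handled
#' transparently. The columns `total_score`, `interface_delta_X` (alias
#' `interface_score`) and `ligand_rms` (aliases `ligand_rmsd`, `rms`) are
#' required, plus a model identifier column `description` (alias
#' `model_id`); `column_map` renames non-standard headers. Rows with
#' non-numeric score entries are dropped with a warning carrying the count.
#'
#' @param path path to the score table.
#' @param column_map optional named character vector mapping standard names
#'   (`model_id`, `total_score`, `interface_score`, `ligand_rmsd`) to the
#'   file's header names.
#' @return a `ligdyn_funnel`; the number of dropped rows is attached as
#'   attribute `n_dropped`.
#' @export
read_score_table <- function(path, column_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- sub("^SCORE:\\s*", "", lines)
  sep <- if (grepl(",", lines[1], fixed = TRUE)) "," else ""
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fill = TRUE,
                          comment.char = "")
  std <- c(model_id = "model_id", total_score = "total_score",
           interface_score = "interface_score", ligand_rmsd = "ligand_rmsd")
  aliases <- list(model_id = c("model_id", "description", "model"),
                  total_score = "total_score",
                  interface_score = c("interface_score", "interface_delta_X"),
                  ligand_rmsd = c("ligand_rmsd", "ligand_rms", "rms"))
  cols <- vapply(names(std), function(key) {
    if (!is.null(column_map) && key %in% names(column_map))
      return(column_map[[key]])
    hit <- intersect(aliases[[key]], names(df))
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  missing_cols <- names(cols)[is.na(cols) | !(cols %in% names(df))]
  if (length(missing_cols))
    stop("score table is missing column(s) ", paste(missing_cols, collapse = ", "),
         "; available headers: ", paste(names(df), collapse = ", "))
  num <- lapply(cols[-1], function(cn) suppressWarnings(as.numeric(df[[cn]])))
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad)) warning(sum(bad), " row(s) with non-numeric scores dropped")
  keep <- !bad
  ens <- funnel_ensemble(df[[cols["model_id"]]][keep],
                         num$total_score[keep],
                         num$interface_score[keep],
                         num$ligand_rmsd[keep])
  attr(ens, "n_dropped") <- sum(bad)
  ens
}

#' Two-stage top-model selection
#'
#' First keep the `n_by_total` models with lowest total score, then the
#' `n_by_interface` with lowest interface (binding) score among those.
#' Ties are broken by (score, then model id lexicographically), so the
#' result is deterministic and independent of input row order.
#'
#' @param ens a `ligdyn_funnel`.
#' @param n_by_total size of the first (total-score) cut.
#' @param n_by_interface size of the second (interface-score) cut; must
#'   not exceed `n_by_total`.
#' @return a `ligdyn_funnel` of `n_by_interface` models, ordered by
#'   ascending interface score.
#' @export
select_top_models <- function(ens, n_by_total = 1000, n_by_interface = 10) {
  stopifnot(inherits(ens, "ligdyn_funnel"))
  n <- length(ens$model_ids)
  if (n_by_total > n) stop("n_by_total exceeds ensemble size")
  if (n_by_interface > n_by_total) stop("n_by_interface exceeds n_by_total")
  o1 <- order(ens$total_score, ens$model_ids)[seq_len(n_by_total)]
  o2 <- o1[order(ens$interface_score[o1], ens$model_ids[o1])][seq_len(n_by_interface)]
  funnel_ensemble(ens$model_ids[o2], ens$total_score[o2],
                  ens$interface_score[o2], ens$ligand_rmsd[o2])
}

#' Pnear funnel statistic
#'
#' Boltzmann-weighted Gaussian of the ligand RMSDs (see the module header
#' for the expression). Energies are shifted by their minimum before
#' exponentiation — Pnear is invariant to uniform energy shifts and the
#' shift guards against overflow. The interface (binding) score is the
#' energy by convention here.
#'
#' @param ens a `ligdyn_funnel`.
#' @param params a `ligdyn_pnear_params` (default lambda 1.5 A, kBT 0.62).
#' @param energy which score column to use as E_i: "interface" (default)
#'   or "total".
#' @return Pnear in [0, 1].
#' @export
pnear <- function(ens, params = pnear_params(), energy = c("interface", "total")) {
  stopifnot(inherits(ens, "ligdyn_funnel"))
  energy <- match.arg(energy)
  e <- if (energy == "interface") ens$interface_score else ens$total_score
  if (!length(e)) stop("empty ensemble")
  e <- e - min(e)
  w <- exp(-e / params$kBT)
  sum(exp(-ens$ligand_rmsd^2 / params$lambda^2) * w) / sum(w)
}

#' Funnel report: Pnear, top models, and score-vs-RMSD scatter data
#'
#' Bundles the quantities a docking-funnel figure needs: the Pnear value,
#' the two-stage top-model table, the reference model (lowest interface
#' score, i.e. the reference pose), and the full scatter of score vs
#' unsuperimposed ligand RMSD.
#'
#' @param ens a `ligdyn_funnel`.
#' @param params a `ligdyn_pnear_params`.
#' @param n_by_total,n_by_interface the two selection cuts (defaults 1000
#'   and 10, capped at the ensemble size).
#' @return list of class `ligdyn_funnel_report` with elements `pnear`,
#'   `reference_model`, `top_models` (data.frame), and `scatter`
#'   (data.frame model_id, total_score, interface_score, ligand_rmsd).
#' @export
funnel_report <- function(ens, params = pnear_params(),
                          n_by_total = 1000, n_by_interface = 10) {
  stopifnot(inherits(ens, "ligdyn_funnel"))
  n <- length(ens$model_ids)
  n_by_total <- min(n_by_total, n)
  n_by_interface <- min(n_by_interface, n_by_total)
  top <- select_top_models(ens, n_by_total, n_by_interface)
  ref <- top$model_ids[1]
  scatter <- data.frame(model_id = ens$model_ids,
                        total_score = ens$total_score,
                        interface_score = ens$interface_score,
                        ligand_rmsd = ens$ligand_rmsd,
                        stringsAsFactors = FALSE)
  top_df <- data.frame(model_id = top$model_ids,
                       total_score = top$total_score,
                       interface_score = top$interface_score,
                       ligand_rmsd = top$ligand_rmsd,
                       stringsAsFactors = FALSE)
  structure(list(pnear = pnear(ens, params), reference_model = ref,
                 top_models = top_df, scatter = scatter, params = params),
            class = "ligdyn_funnel_report")
}

#' @export
print.ligdyn_funnel_report <- function(x, ...) {
  cat(sprintf("ligdyn funnel report: %d models, Pnear = %.4f (lambda %.2f, kBT %.2f)\n",
              nrow(x$scatter), x$pnear, x$params$lambda, x$params$kBT))
  cat("reference model (lowest interface score):", x$reference_model, "\n")
  cat("top models:\n")
  print(utils::head(x$top_models, 10))
  invisible(x)
}

## ----------------------------------------------- energy decomposition

#' Read a per-residue energy-decomposition table
#'
#' TSV with columns `chain`, `resid`, `resname`, `replicate`, `dG`
#' (kcal/mol): one row per residue per replicate.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_decomposition_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chain", "resid", "resname", "replicate", "dG")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("decomposition table missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Aggregate per-residue energy decomposition across replicates
#'
#' Averages per-residue binding-energy contributions over replicate
#' trajectories and filters to residues whose mean magnitude exceeds a
#' thermal-energy cutoff (kT, about 0.6 kcal/mol at 300 K) — the
#' convention for reporting only energetically meaningful contributors.
#'
#' @param tables a single decomposition data.frame, or a list of
#'   per-replicate data.frames (each with columns chain, resid, resname,
#'   dG; a `replicate` column is optional within a list element).
#' @param kT_cut magnitude threshold in kcal/mol (strict `|mean| > kT_cut`);
#'   default 0.6.
#' @return data.frame (chain, resid, resname, mean_dG, sd_dG, n_replicates)
#'   filtered and sorted by ascending mean_dG (strongest stabilisation
#'   first). Residues missing from some replicates are kept, averaged over
#'   the replicates where they appear, with `incomplete = TRUE` and a
#'   warning.
#' @export
aggregate_decomposition <- function(tables, kT_cut = 0.6) {
  if (is.data.frame(tables)) {
    if (is.null(tables$replicate)) tables$replicate <- 1
    tables <- split(tables, tables$replicate)
  }
  if (!length(tables)) stop("no decomposition tables supplied")
  n_rep <- length(tables)
  long <- do.call(rbind, lapply(seq_along(tables), function(k) {
    t <- tables[[k]]
    data.frame(key = paste(t$chain, t$resid, t$resname, sep = "|"),
               chain = t$chain, resid = t$resid, resname = t$resname,
               dG = t$dG, stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(long, long$key), function(g) {
    data.frame(chain = g$chain[1], resid = g$resid[1], resname = g$resname[1],
               mean_dG = mean(g$dG),
               sd_dG = if (nrow(g) > 1) stats::sd(g$dG) else 0,
               n_replicates = nrow(g),
               incomplete = nrow(g) < n_rep,
               stringsAsFactors = FALSE)
  }))
  if (any(agg$incomplete))
    warning(sum(agg$incomplete),
            " residue(s) present in only a subset of replicates")
  agg <- agg[abs(agg$mean_dG) > kT_cut, , drop = FALSE]
  agg <- agg[order(agg$mean_dG), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Check the component bookkeeping of a binding free energy record
#'
#' For one complex, the gas-phase and solvation terms must close:
#' dG_gas = dE_ele + dE_vdw, dG_sol = dG_pol + dG_np, and
#' dG_bind = dG_gas + dG_sol, each within a tolerance.
#'
#' @param components named numeric vector with entries dE_ele, dE_vdw,
#'   dG_pol, dG_np, dG_gas, dG_sol, dG_bind (kcal/mol).
#' @param tol closure tolerance in kcal/mol (default 0.2).
#' @return TRUE invisibly, or an error naming the identity that fails.
#' @export
check_decomposition_components <- function(components, tol = 0.2) {
  need <- c("dE_ele", "dE_vdw", "dG_pol", "dG_np", "dG_gas", "dG_sol", "dG_bind")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("missing components: ", paste(miss, collapse = ", "))
  x <- components
  if (abs(x["dE_ele"] + x["dE_vdw"] - x["dG_gas"]) > tol)
    stop("gas-phase components do not sum to dG_gas within ", tol, " kcal/mol")
  if (abs(x["dG_pol"] + x["dG_np"] - x["dG_sol"]) > tol)
    stop("solvation components do not sum to dG_sol within ", tol, " kcal/mol")
  if (abs(x["dG_gas"] + x["dG_sol"] - x["dG_bind"]) > tol)
    stop("dG_gas + dG_sol does not equal dG_bind within ", tol, " kcal/mol")
  invisible(TRUE)
}

#' Residues within a distance shell of the ligand
#'
#' Helper for the per-residue decomposition shell: returns the (chain,
#' resid) pairs of protein residues with any heavy atom within `cutoff` of
#' any ligand heavy atom in a given frame.
#'
#' @param traj a `ligdyn_trajectory`.
#' @param frame frame index.
#' @param ligand a `ligdyn_selection` of ligand atoms.
#' @param cutoff shell radius in Angstrom (default 5).
#' @return data.frame (chain, resid, resname, min_dist).
#' @export
residue_shell <- function(traj, frame = 1, ligand, cutoff = 5) {
  at <- traj$topology$atoms
  x <- frame_coords(traj, frame)
  li <- sel_indices(ligand, nrow(at))
  heavy <- toupper(at$element) != "H"
  lig_x <- x[intersect(li, which(heavy)), , drop = FALSE]
  prot <- setdiff(which(heavy & at$resname %in% STANDARD_AA), li)
  if (!length(prot)) return(data.frame(chain = character(0), resid = integer(0),
                                       resname = character(0), min_dist = numeric(0)))
  key <- paste(at$chain[prot], at$resid[prot], sep = "|")
  out <- do.call(rbind, lapply(split(prot, key), function(ri) {
    d <- min_cross_dist(x[ri, , drop = FALSE], lig_x)
    data.frame(chain = at$chain[ri[1]], resid = at$resid[ri[1]],
               resname = at$resname[ri[1]], min_dist = d,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$min_dist <= cutoff, , drop = FALSE]
  out <- out[order(out$min_dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}
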