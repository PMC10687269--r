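#' Desk-scale study configurations
#'
#' The model and training settings used throughout the package's synthetic
#' experiments (tests, vignette, acceptance script): small 32-wide encoders
#' matched to the synthetic benchmark's 32-dimensional residue features, two
#' inner adaptation steps, three critic ascent steps, fixed multi-step
#' weights that keep most of the mass on the unadapted parameters (the
#' zero-shot operating point), Adam outer updates with a cosine-annealed
#' rate, and task attention with a damped learning rate. The full-scale
#' defaults of [base_config()] and [meta_config()] are untouched by this
#' helper.
#'
#' @param outer_steps outer optimization steps (default 300)
#' @param sib base-model mode, see [base_config()]
#' @param attention task-attention switch, see [meta_config()]
#' @return list with elements `base` and `meta`
#' @export
desk_scale_configs <- function(outer_steps = 300L, sib = "sib",
                               attention = TRUE) {
  list(
    base = base_config(
      protein_widths = c(32L, 32L, 32L), molecule_embed_dim = 32L,
      molecule_widths = c(32L, 32L), assign_hidden = 32L,
      critic_hidden = c(32L, 16L), classifier_hidden = c(32L, 16L),
      mi_inner_steps = 3L, sib = sib, sub_pool = "mean"
    ),
    meta = meta_config(
      inner_steps = 2L, meta_lr = 0.02, batch_size = 4L, k = 5L, m = 5L,
      outer_steps = as.integer(outer_steps), attention = attention,
      attention_dim = 16L, lslr_init = 0.05, upsilon = c(0.7, 0.15, 0.15)
    )
  )
}

#' Run the full synthetic study for one seed
#'
#' Generates the planted-pocket benchmark, builds the cluster/scaffold
#' splits, meta-trains on up to `n_train` training-cluster proteins with the
#' transductive split as the model-selection validation set, and evaluates
#' zero-shot AUROC/AUPRC and pocket overlap on the held-out inductive
#' proteins. This is the end-to-end experiment the vignette and the
#' acceptance script report.
#'
#' @param seed integer seed driving the benchmark, the splits and training
#' @param outer_steps training length
#' @param n_train cap on training task proteins
#' @param n_eval number of inductive proteins evaluated (those with the most
#'   held-out records and both classes present)
#' @param sib,attention model switches forwarded to [desk_scale_configs()]
#' @return list with the trained `model`, the `benchmark`, the `splits`, and
#'   an `evaluation` list (per-protein AUROC table, pocket-overlap tibble)
#' @export
run_synthetic_study <- function(seed, outer_steps = 300L, n_train = 40L,
                                n_eval = 8L, sib = "sib", attention = TRUE) {
  bench <- make_benchmark(synthetic_spec(seed = seed))
  sb <- make_splits(bench$records, bench$truth$family_of,
                    bench$truth$scaffold_of, train_scaffold_ratio = 0.6,
                    min_molecules = 20L, seed = seed)
  cfg <- desk_scale_configs(outer_steps = outer_steps, sib = sib,
                            attention = attention)
  model <- meta_train(sb$train, bench$proteins, bench$molecules,
                      cfg$base, cfg$meta, max_train_proteins = n_train,
                      validation = sb$transductive, eval_every = 25L,
                      seed = seed)
  ev <- evaluate_inductive(model, bench, sb, n_eval = n_eval, seed = seed)
  list(model = model, benchmark = bench, splits = sb, evaluation = ev)
}

#' Zero-shot evaluation on the inductive proteins of a synthetic study
#'
#' @param model a trained `metabind_model`
#' @param bench the `synthetic_benchmark`
#' @param splits the `split_bundle`
#' @param n_eval number of inductive proteins (most records first)
#' @param seed seed for the random-baseline pockets
#' @return list with `per_protein` (tibble: protein_id, n, auroc, auprc) and
#'   `pockets` (tibble: protein_id, molecule_id, jaccard, jaccard_random,
#'   neighbor_jaccard)
#' @export
evaluate_inductive <- function(model, bench, splits, n_eval = 8L, seed = 1L) {
  ind <- splits$inductive
  ord <- names(sort(table(ind$protein_id), decreasing = TRUE))
  rows <- list()
  pockets <- list()
  withr::with_seed(seed + 10000L, {
    for (pid in ord) {
      r <- ind[ind$protein_id == pid, , drop = FALSE]
      if (length(unique(r$label)) < 2L) next
      pred <- predict_zero_shot(model, bench$proteins[[pid]],
                                bench$molecules[r$molecule_id])
      rows[[pid]] <- tibble::tibble(
        protein_id = pid, n = nrow(r),
        auroc = auroc(r$label, pred$score),
        auprc = auprc(r$label, pred$score)
      )
      Zl <- attr(pred, "Z")
      truth <- bench$truth$pockets[[pid]]
      g <- bench$proteins[[pid]]
      for (jj in which(r$label == "binding")) {
        pk <- extract_pocket(Zl[[jj]], protein_id = pid)
        pockets[[length(pockets) + 1L]] <- tibble::tibble(
          protein_id = pid, molecule_id = r$molecule_id[jj],
          jaccard = jaccard(pk, truth),
          jaccard_random = jaccard(
            random_pocket(g$n_residues, length(truth)), truth),
          neighbor_jaccard = neighbor_jaccard(pk, truth, g)
        )
      }
      if (length(rows) >= n_eval) break
    }
  })
  list(per_protein = dplyr::bind_rows(rows),
       pockets = dplyr::bind_rows(pockets))
}

#' Few-shot fine-tuning comparison on held-out proteins
#'
#' For up to `n_proteins` proteins of the combined semi-inductive and
#' inductive sets, fine-tunes the meta-model on a 5+5 set and compares
#' per-protein AUROC on the protein's remaining records against the
#' zero-shot scores.
#'
#' @param model a trained `metabind_model`
#' @param bench the `synthetic_benchmark`
#' @param splits the `split_bundle`
#' @param n_proteins number of proteins compared
#' @param steps,lr fine-tuning schedule
#' @param seed seed for the few-shot sampling
#' @return tibble (protein_id, auroc_zero_shot, auroc_fine_tuned)
#' @export
evaluate_fewshot <- function(model, bench, splits, n_proteins = 20L,
                             steps = 20L, lr = 0.01, seed = 1L) {
  fs <- make_fewshot(splits$semi_inductive, splits$inductive, seed = seed)
  out <- list()
  for (pid in names(fs$finetune)) {
    te <- fs$test[[pid]]
    if (length(unique(te$label)) < 2L) next
    protein <- bench$proteins[[pid]]
    z <- predict_zero_shot(model, protein, bench$molecules[te$molecule_id])
    ft_rec <- fs$finetune[[pid]]
    ft <- fine_tune(model, protein, bench$molecules[ft_rec$molecule_id],
                    as.numeric(ft_rec$label == "binding"),
                    steps = steps, lr = lr)
    f <- predict_zero_shot(ft, protein, bench$molecules[te$molecule_id])
    out[[pid]] <- tibble::tibble(
      protein_id = pid,
      auroc_zero_shot = auroc(te$label, z$score),
      auroc_fine_tuned = auroc(te$label, f$score)
    )
    if (length(out) >= n_proteins) break
  }
  dplyr::bind_rows(out)
}
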