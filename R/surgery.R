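# Architecture surgery: graft new study conditions onto a frozen reference
# model and fine-tune at one of three granularities.

study_seed <- function(model_seed, label, extra = 0L) {
  substream_seed(model_seed, "adaptor", label, extra)
}

#' Add new study conditions to a trained model
#'
#' Extends the condition registry by `new_studies` and appends one freshly
#' initialized weight row per study to the first encoder layer (a p-vector)
#' and the first decoder layer (a q-vector) — the adaptor. Initialization is
#' Glorot-scale Gaussian, seeded per study label, so grafting is independent
#' of the order and of any other grafted study. Every pre-existing parameter
#' is left bit-identical.
#'
#' @param model an `scgraft_model`.
#' @param new_studies character vector of study labels not yet in the
#'   registry.
#' @return the extended model (new rows marked frozen until [set_freeze()]).
#' @export
expand_conditions <- function(model, new_studies) {
  new_studies <- as.character(new_studies)
  if (anyDuplicated(new_studies))
    stop("duplicate labels in new_studies")
  clash <- intersect(new_studies, model$registry)
  if (length(clash))
    stop("study already in registry: ", paste(clash, collapse = ", "))
  if (length(new_studies) == 0) return(model)
  p <- ncol(model$par$enc_s); q <- ncol(model$par$dec_s)
  for (lab in new_studies) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(study_seed(model$config$seed, lab))
    row_e <- stats::rnorm(p, 0, sqrt(2 / (length(model$genes) + p)))
    row_d <- stats::rnorm(q, 0, sqrt(2 / (model$config$latent_dim + q)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    model$par$enc_s <- rbind(model$par$enc_s, row_e, deparse.level = 0)
    model$par$dec_s <- rbind(model$par$dec_s, row_d, deparse.level = 0)
    model$frozen$enc_s <- rbind(model$frozen$enc_s, rep(TRUE, p),
                                deparse.level = 0)
    model$frozen$dec_s <- rbind(model$frozen$dec_s, rep(TRUE, q),
                                deparse.level = 0)
    model$registry <- c(model$registry, lab)
    model$new_studies <- c(model$new_studies, lab)
  }
  model
}

#' Set the fine-tuning granularity by freezing parameters
#'
#' Three granularities: `"adaptors"` trains only the grafted condition rows
#' (`m * (p + q)` scalars for `m` new studies); `"first_layers"` trains the
#' entire first layer of encoder and decoder (input weights and all condition
#' rows) with everything deeper frozen; `"full"` trains all parameters.
#'
#' @param model an `scgraft_model` with at least one grafted study (not
#'   required for `"full"` on a pristine reference).
#' @param strategy `"adaptors"`, `"first_layers"` or `"full"`.
#' @return the model with its frozen mask set.
#' @export
set_freeze <- function(model, strategy = c("adaptors", "first_layers", "full")) {
  strategy <- match.arg(strategy)
  if (strategy != "full" && length(model$new_studies) == 0)
    stop("model has no grafted studies; run expand_conditions() first")
  all_true <- lapply(model$par, function(x) { m <- x; m[] <- TRUE
    storage.mode(m) <- "logical"; m })
  all_false <- lapply(model$par, function(x) { m <- x; m[] <- FALSE
    storage.mode(m) <- "logical"; m })
  frozen <- switch(strategy,
    full = all_false,
    adaptors = {
      f <- all_true
      new_rows <- match(model$new_studies, model$registry)
      f$enc_s[new_rows, ] <- FALSE
      f$dec_s[new_rows, ] <- FALSE
      f
    },
    first_layers = {
      f <- all_true
      f$enc_x[] <- FALSE; f$enc_s[] <- FALSE
      f$dec_z[] <- FALSE; f$dec_s[] <- FALSE
      f
    })
  model$frozen <- frozen
  model$strategy <- strategy
  model
}

#' Count trainable (unfrozen) scalar parameters
#' @param model an `scgraft_model`.
#' @return integer count; in adaptors mode equals `m * (p + q)`.
#' @export
count_trainable <- function(model) {
  sum(vapply(model$frozen, function(m) sum(!m), 0))
}

#' Fine-tune a model on query data
#'
#' Optimizes the model objective on the query cells only, updating only the
#' unfrozen parameters for the chosen strategy. In `"adaptors"` mode each
#' query study is trained independently on its own cells with a seed derived
#' from its label: since a study's adaptor rows are the only parameters its
#' cells touch and all shared weights are frozen, mapping several studies —
#' in one call or in any order of calls — yields identical results, and the
#' embedding of reference cells is exactly unchanged.
#'
#' @param model an `scgraft_model` whose registry already contains the query
#'   studies as grafted conditions (see [expand_conditions()]).
#' @param query an [sc_dataset] of query cells (genes aligned to the model).
#' @param strategy fine-tuning granularity, see [set_freeze()].
#' @param epochs training epochs (default: the model config's).
#' @param seed base seed for non-adaptor strategies and epoch shuffling.
#' @param verbose print per-epoch loss?
#' @return the fine-tuned `scgraft_model`.
#' @export
finetune_query <- function(model, query,
                           strategy = c("adaptors", "first_layers", "full"),
                           epochs = model$config$epochs,
                           seed = model$config$seed, verbose = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(query, "sc_dataset"))
  if (!identical(query$genes, model$genes))
    stop("query genes do not match the model gene list; run align_genes()")
  qs <- query$studies
  in_ref <- intersect(qs, model$reference_studies)
  if (length(in_ref))
    stop("query contains reference study label: ",
         paste(in_ref, collapse = ", "))
  missing <- setdiff(qs, model$registry)
  if (length(missing))
    stop("query study not grafted: ", paste(missing, collapse = ", "),
         " (run expand_conditions first)")
  model <- set_freeze(model, strategy)
  if (epochs == 0) return(model)
  cfg <- model$config
  inp <- model_input(query, cfg$likelihood)
  if (strategy == "adaptors") {
    # independent per-study sub-problems; exact commutativity by construction
    for (lab in sort(qs)) {
      rows <- which(query$cell_meta$study == lab)
      sidx <- rep(match(lab, model$registry), length(rows))
      set.seed(study_seed(cfg$seed, lab, extra = seed))
      fit <- adam_train(model$par, model$frozen, cfg,
                        inp$X[rows, , drop = FALSE], sidx,
                        inp$target[rows, , drop = FALSE], inp$lib[rows],
                        epochs = epochs, beta = 0, verbose = verbose)
      model$par <- fit$par
      model$history <- c(model$history, fit$history)
    }
  } else {
    sidx <- match(query$cell_meta$study, model$registry)
    set.seed(seed)
    fit <- adam_train(model$par, model$frozen, cfg, inp$X, sidx, inp$target,
                      inp$lib, epochs = epochs, verbose = verbose)
    model$par <- fit$par
    model$history <- c(model$history, fit$history)
  }
  model
}

#' Map a query dataset onto a reference model (graft + fine-tune)
#'
#' Convenience wrapper: aligns the query genes to the model, grafts every
#' query study not yet in the registry, fine-tunes with [finetune_query()],
#' and returns the updated model together with the query embedding.
#'
#' @inheritParams finetune_query
#' @return list with `model` and `embedding` (a `latent_embedding` of the
#'   query cells).
#' @export
surgery <- function(model, query,
                    strategy = c("adaptors", "first_layers", "full"),
                    epochs = model$config$epochs,
                    seed = model$config$seed, verbose = FALSE) {
  strategy <- match.arg(strategy)
  if (!identical(query$genes, model$genes))
    query <- align_genes(query, model$genes)
  model <- expand_conditions(model, setdiff(query$studies, model$registry))
  model <- finetune_query(model, query, strategy = strategy, epochs = epochs,
                          seed = seed, verbose = verbose)
  list(model = model, embedding = embed(model, query))
}
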