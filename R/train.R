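#' Training configuration
#'
#' Defaults are the full-scale protocol: 10 epochs of AdamW (decoupled
#' weight decay) starting at learning rate 3e-5 and decayed multiplicatively
#' by 13% after each epoch — so the rate roughly halves every five epochs
#' (0.87^5 = 0.498) — with batch size 64 and no early stopping: the
#' last-epoch weights are the final model.
#'
#' @param epochs Number of epochs (>= 1).
#' @param lr Initial learning rate.
#' @param lr_decay Per-epoch multiplicative decay factor in (0, 1).
#' @param batch_size Examples per optimizer step.
#' @param weight_decay AdamW decoupled weight-decay coefficient.
#' @param seed Seed for shuffling (per-epoch, derived deterministically).
#' @param verbose Print per-epoch losses.
#' @return A list of class `chromattn_train_config`.
#' @export
train_config <- function(epochs = 10L, lr = 3e-5, lr_decay = 0.87,
                         batch_size = 64L, weight_decay = 0.01,
                         seed = 1L, verbose = FALSE) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr_decay <= 0 || lr_decay >= 1) stop("lr_decay must be in (0, 1)")
  structure(list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "chromattn_train_config")
}

#' Learning rate at a given epoch
#'
#' `lr * decay^epoch` with 0-based epochs: the first epoch runs at the
#' initial rate and five decays take it to about half.
#'
#' @param lr Initial learning rate.
#' @param epoch 0-based epoch index.
#' @param decay Per-epoch factor (default 0.87).
#' @return The learning rate.
#' @export
lr_schedule <- function(lr, epoch, decay = 0.87) lr * decay^epoch

# ---- AdamW ----

adamw_state <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- list()
  st$v <- list()
  st
}

adamw_step <- function(params, grads, st, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- st$m[[nm]]
    v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[nm]] <- m
    st$v[[nm]] <- v
    params[[nm]] <- params[[nm]] -
      lr * ((m / c1) / (sqrt(v / c2) + eps) + weight_decay * params[[nm]])
  }
  params
}

# mean loss over a set of examples (no gradients)
mean_loss <- function(model, examples) {
  task <- model$config$task
  tot <- 0
  for (ex in examples) {
    out <- chromoformer_forward(model, ex)$output
    lab <- if (task == "clf") as.integer(ex$label) else ex$label
    tot <- tot + loss_and_grad(out, lab, task)$loss
  }
  tot / length(examples)
}

#' Train a model
#'
#' Runs exactly `config$epochs` epochs of mini-batch AdamW with the
#' multiplicative learning-rate schedule and returns the last-epoch weights
#' (no early stopping or best-checkpoint selection). Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model A `chromattn_model` (task `"clf"` or `"reg"`).
#' @param examples Training examples from [featurize_dataset()].
#' @param config A [train_config()].
#' @param val_examples Optional held-out examples; their loss is logged per
#'   epoch (never used for selection).
#' @return `list(model = trained model, history = data.frame(epoch, lr,
#'   train_loss, val_loss))`.
#' @export
train_chromoformer <- function(model, examples, config = train_config(),
                               val_examples = NULL) {
  stopifnot(inherits(config, "chromattn_train_config"))
  task <- model$config$task
  if (task == "diff")
    stop("train_chromoformer() handles clf/reg; pair examples externally for diff")
  st <- adamw_state()
  n <- length(examples)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(config$lr, epoch - 1L, config$lr_decay)
    set.seed(config$seed * 1000L + epoch)
    ord <- sample.int(n)
    ep_loss <- 0
    starts <- seq(1L, n, by = config$batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      gr <- new_grad_store()
      b_loss <- 0
      for (j in idx) {
        ex <- examples[[j]]
        lab <- if (task == "clf") as.integer(ex$label) else ex$label
        b_loss <- b_loss + example_loss_grad(model, ex, lab, gr)
      }
      if (!is.finite(b_loss))
        stop(sprintf("non-finite loss (lr = %g, epoch %d, batch %d)",
                     lr, epoch, bi))
      grads <- grads_as_list(gr)
      nb <- length(idx)
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / nb
      model$params <- adamw_step(model$params, grads, st, lr,
                                 config$weight_decay)
      ep_loss <- ep_loss + b_loss
    }
    vl <- if (!is.null(val_examples)) mean_loss(model, val_examples)
    else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = ep_loss / n,
                                         val_loss = vl))
    if (config$verbose)
      message(sprintf("epoch %d lr=%.3g train=%.4f val=%.4f",
                      epoch, lr, ep_loss / n, vl))
  }
  list(model = model, history = history)
}

#' Predict for a set of examples
#'
#' @param model Trained `chromattn_model`.
#' @param examples Featurized examples.
#' @return Named numeric vector: probability of the high-expression class
#'   for `"clf"`, predicted log2 expression for `"reg"`.
#' @export
predict_genes <- function(model, examples) {
  task <- model$config$task
  out <- vapply(examples, function(ex) {
    z <- chromoformer_forward(model, ex)$output
    if (task == "clf") {
      z <- z - max(z)
      exp(z[2L]) / sum(exp(z))
    } else unname(z)
  }, numeric(1))
  stats::setNames(out, vapply(examples, `[[`, character(1), "gene_id"))
}

# step-function average precision
average_precision <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec * lab) / sum(lab)
}

#' Evaluate predictions against labels
#'
#' Classification: ROC-AUC (via `pROC`), accuracy at 0.5, and average
#' precision; when the validation labels are single-class the AUC is
#' undefined and reported as `NA` with a warning. Regression: Pearson r,
#' R-squared and MSE.
#'
#' @param predictions Numeric vector (class-1 probability or predicted
#'   value).
#' @param labels Numeric vector of true labels/values.
#' @param task `"clf"`, `"reg"` or `"diff"`.
#' @return Named list of metrics.
#' @export
evaluate_predictions <- function(predictions, labels,
                                 task = c("clf", "reg", "diff")) {
  task <- match.arg(task)
  if (task == "clf") {
    if (length(unique(labels)) < 2L) {
      warning("single-class validation labels: AUC undefined")
      return(list(auc = NA_real_,
                  accuracy = mean((predictions > 0.5) == labels),
                  average_precision = NA_real_))
    }
    auc <- as.numeric(pROC::auc(pROC::roc(labels, predictions,
                                          quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    list(auc = auc,
         accuracy = mean((predictions > 0.5) == labels),
         average_precision = average_precision(predictions, labels))
  } else {
    list(pearson = stats::cor(predictions, labels),
         r2 = 1 - sum((predictions - labels)^2) /
           sum((labels - mean(labels))^2),
         mse = mean((predictions - labels)^2))
  }
}

#' Chromosome-disjoint cross-validation
#'
#' Trains one model per fold on the out-of-fold chromosomes and evaluates
#' on the held-out fold, emitting per-fold metric reports, a tidy per-gene
#' out-of-fold prediction table, and (optionally) the embedding bundles of
#' every validation gene under its own fold's model — the inputs for
#' downstream cis-regulatory impact scoring.
#'
#' @param examples Named list from [featurize_dataset()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param seed Base seed; fold-specific weight-init and shuffling seeds are
#'   derived from it.
#' @param folds Optional precomputed [make_cv_folds()] result.
#' @param keep_bundles Collect embedding bundles for validation genes.
#' @param keep_models Keep the k trained models in the result.
#' @return `list(reports, predictions, bundles, folds, models, histories)`.
#' @export
run_cv <- function(examples, model_cfg, train_cfg, k = 4L, seed = 1L,
                   folds = NULL, keep_bundles = TRUE, keep_models = FALSE) {
  genes <- data.frame(
    gene_id = vapply(examples, `[[`, character(1), "gene_id"),
    chrom = vapply(examples, `[[`, character(1), "chrom"))
  if (is.null(folds)) folds <- make_cv_folds(genes, k, seed)
  k <- length(folds$folds)
  reports <- vector("list", k)
  histories <- vector("list", k)
  models <- vector("list", k)
  bundles <- list()
  preds <- list()
  for (f in seq_len(k)) {
    val_ids <- folds$folds[[f]]
    train_ex <- examples[!(names(examples) %in% val_ids)]
    val_ex <- examples[names(examples) %in% val_ids]
    model <- build_chromoformer(model_cfg, seed = seed + f)
    tc <- train_cfg
    tc$seed <- train_cfg$seed + 100L * f
    fit <- train_chromoformer(model, train_ex, tc)
    histories[[f]] <- fit$history
    p <- predict_genes(fit$model, val_ex)
    lab <- vapply(val_ex, `[[`, numeric(1), "label")
    reports[[f]] <- evaluate_predictions(p, lab, model_cfg$task)
    preds[[f]] <- data.frame(gene_id = names(p), fold = f,
                             label = unname(lab), prediction = unname(p))
    if (keep_bundles) {
      for (ex in val_ex) {
        b <- chromoformer_forward(fit$model, ex, bundle = TRUE)$bundle
        b$attention <- NULL # keep bundles light; maps available on demand
        bundles[[ex$gene_id]] <- b
      }
    }
    if (keep_models) models[[f]] <- fit$model
  }
  list(reports = reports, predictions = do.call(rbind, preds),
       bundles = bundles, folds = folds,
       models = if (keep_models) models else NULL,
       histories = histories)
}
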