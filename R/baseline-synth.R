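## Column metadata so synthetic values come back in the training type.
columnMeta <- function(x) {
  if (is.numeric(x)) list(type = "numeric")
  else list(type = "factor", levels = levels(as.factor(x)))
}

asModelFrame <- function(df, columns) {
  for (nm in names(columns)) {
    if (!nm %in% names(df)) next
    df[[nm]] <- if (columns[[nm]]$type == "numeric") as.numeric(df[[nm]])
                else factor(df[[nm]], levels = columns[[nm]]$levels)
  }
  df
}

## Fit one conditional: tree on `preds`, donor pools per leaf; marginal
## fallback when the response or every predictor is constant (logged).
fitConditional <- function(df, target, preds, minLeaf) {
  y <- df[[target]]
  usable <- preds[vapply(df[preds], function(p) length(unique(p)) > 1, TRUE)]
  if (length(usable) && length(unique(y)) > 1) {
    fml <- stats::as.formula(paste(target, "~", paste(usable, collapse = "+")))
    fit <- tryCatch(
      tree::tree(fml, data = df,
                 control = tree::tree.control(nobs = nrow(df),
                                              mincut = minLeaf,
                                              minsize = 2L * minLeaf)),
      error = function(e) NULL)
    if (!is.null(fit) && nrow(fit$frame) >= 2)
      return(list(kind = "tree", fit = fit, pools = split(y, fit$where)))
  }
  message("sequential trees: '", target, "' fell back to marginal sampling")
  list(kind = "marginal", pool = y)
}

## Draw one value per row of `partial` from a fitted conditional.
drawConditional <- function(m, partial) {
  n <- nrow(partial)
  if (m$kind == "marginal") return(sample(m$pool, n, replace = TRUE))
  leaf <- predict(m$fit, newdata = partial, type = "where")
  val <- m$pools[[1]][rep(NA_integer_, n)]
  for (lf in unique(leaf)) {
    pool <- m$pools[[as.character(lf)]]
    sel <- which(leaf == lf)
    val[sel] <- sample(pool, length(sel), replace = TRUE)
  }
  val
}

#' Fit a sequential tree-based synthesizer
#'
#' Variables are synthesized one at a time in `order`: the first from its
#' empirical marginal, each later variable from a classification/regression
#' tree on all earlier variables, with the observed values pooled per leaf
#' as donors. Sampling from leaf donor pools (rather than parametric leaf
#' models) means synthetic values are always values that occurred in the
#' training data, and preserves within-leaf distributions without
#' distributional assumptions. Used to seed the recurrent generator with
#' baseline characteristics and first-event values that reproduce the
#' population's starting conditions better than randomly sampled starts.
#'
#' @param data data.frame of baseline (and first-event) variables; character
#'   columns are treated as factors.
#' @param order synthesis order; default the column order of `data`.
#' @param minLeaf minimum donor-pool (leaf) size; default 5.
#' @return a \linkS4class{SequentialTreeModel}.
#' @export
fitSequentialTrees <- function(data, order = names(data), minLeaf = 5L) {
  assertThat(nrow(data) > 0, "empty training table")
  assertThat(setequal(order, names(data)) && !anyDuplicated(order),
             "order must be a permutation of the columns")
  columns <- lapply(data[order], columnMeta)
  df <- asModelFrame(data[order], columns)
  models <- vector("list", length(order))
  names(models) <- order
  models[[1]] <- list(kind = "marginal", pool = df[[1]])
  for (j in seq_along(order)[-1])
    models[[j]] <- fitConditional(df, order[j], order[seq_len(j - 1)],
                                  minLeaf)
  new("SequentialTreeModel", order = order, models = models,
      columns = columns, minLeaf = as.integer(minLeaf))
}

#' Synthesize rows from a sequential tree model
#'
#' Draws `n` rows: variable 1 is resampled from its marginal; each later
#' variable is obtained by routing the partial synthetic row down its fitted
#' tree and resampling from the donor pool of the reached leaf.
#'
#' @param model a \linkS4class{SequentialTreeModel}.
#' @param n number of rows.
#' @param seed RNG seed.
#' @return data.frame with the training columns, in training column types
#'   (factors returned as character).
#' @export
synthesizeBaseline <- function(model, n, seed = 1L) {
  assertThat(n >= 0, "n must be non-negative")
  ord <- model@order
  out <- stats::setNames(
    as.data.frame(replicate(length(ord), rep(NA, n), simplify = FALSE)), ord)
  withSeed(seed, {
    for (j in seq_along(ord)) {
      m <- model@models[[j]]
      if (n == 0) { out[[j]] <- m$pool[0]; next }
      out[[j]] <- if (j == 1 || m$kind == "marginal") {
        sample(if (m$kind == "marginal") m$pool else m$pool, n, replace = TRUE)
      } else {
        drawConditional(m, asModelFrame(out[, seq_len(j - 1), drop = FALSE],
                                        model@columns[seq_len(j - 1)]))
      }
    }
  })
  for (nm in ord)   # factors back to character for Cohort-style tables
    if (model@columns[[nm]]$type == "factor")
      out[[nm]] <- as.character(out[[nm]])
  out
}

#' Baseline + first-event table used for generator seeding
#'
#' Extracts, per individual, the baseline variables, the first event's label
#' and the first event's attribute values (missing where irrelevant): the
#' table the sequential tree synthesizer is fitted on.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @return data.frame with the baseline columns, `first_label` and
#'   `first_<attr>` columns.
#' @export
seedTable <- function(cohort) {
  sc <- cohort@schema
  e <- cohort@events
  first <- e[e$position == 1L, , drop = FALSE]
  first <- first[match(cohort@baseline$patient_id, first$patient_id), ]
  out <- cohort@baseline[, baselineNames(sc), drop = FALSE]
  out$first_label <- first$label
  for (a in attributeNames(sc)) out[[paste0("first_", a)]] <- first[[a]]
  out <- out[!is.na(out$first_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the full generator-seeding synthesizer for a cohort
#'
#' Fits the sequential trees over baseline variables then the first-event
#' label (the default synthesis order), plus one conditional per first-event
#' attribute fitted only on the individuals whose first label makes that
#' attribute relevant; at synthesis time an attribute is drawn only when the
#' synthesized first label makes it relevant, and is missing otherwise —
#' mirroring the masking the recurrent model applies at every later step.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param minLeaf minimum leaf size (default 5).
#' @return an object of class `seedSynthesizer` for [synthesizeSeeds()].
#' @export
fitSeedSynthesizer <- function(cohort, minLeaf = 5L) {
  sc <- cohort@schema
  st <- seedTable(cohort)
  mainCols <- c(baselineNames(sc), "first_label")
  main <- fitSequentialTrees(st[mainCols], minLeaf = minLeaf)
  attrModels <- list()
  attrColumns <- list()
  mainColumns <- main@columns
  for (a in attributeNames(sc)) {
    col <- paste0("first_", a)
    rel <- !is.na(st[[col]])
    if (!any(rel)) { attrModels[a] <- list(NULL); next }
    sub <- st[rel, c(mainCols, col)]
    cols <- c(mainColumns, stats::setNames(list(columnMeta(sub[[col]])), col))
    df <- asModelFrame(sub, cols)
    attrModels[[a]] <- fitConditional(df, col, mainCols, minLeaf)
    attrColumns[[a]] <- cols[[col]]
  }
  structure(list(schema = sc, main = main, attrModels = attrModels,
                 attrColumns = attrColumns, mainCols = mainCols),
            class = "seedSynthesizer")
}

#' Synthesize generator seeds (baseline + first event)
#'
#' @param synth a `seedSynthesizer` from [fitSeedSynthesizer()].
#' @param n number of synthetic individuals.
#' @param seed RNG seed.
#' @return data.frame in the [seedTable()] layout, ready for
#'   [generateCohort()].
#' @export
synthesizeSeeds <- function(synth, n, seed = 1L) {
  sc <- synth$schema
  out <- synthesizeBaseline(synth$main, n, seed = seed)
  rel <- relevanceMap(sc)
  withSeed(childSeed(seed, "seed-attrs"), {
    for (a in attributeNames(sc)) {
      col <- paste0("first_", a)
      relevant <- vapply(out$first_label, function(l)
        a %in% (rel[[l]] %||% character()), TRUE)
      val <- rep(NA, n)
      m <- synth$attrModels[[a]]
      if (any(relevant) && !is.null(m)) {
        partial <- asModelFrame(out[relevant, synth$mainCols, drop = FALSE],
                                synth$main@columns)
        v <- drawConditional(m, partial)
        if (is.factor(v)) v <- as.character(v)
        val[relevant] <- v
      }
      out[[col]] <- val
    }
  })
  out
}

setMethod("show", "SequentialTreeModel", function(object) {
  kinds <- vapply(object@models, `[[`, "", "kind")
  cat("SequentialTreeModel: ", length(object@order), " variables (",
      sum(kinds == "tree"), " trees, ", sum(kinds == "marginal"),
      " marginals), min leaf ", object@minLeaf, "\n", sep = "")
})
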