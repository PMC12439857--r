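# Gradient-boosted tree backend: a thin fit/predict/attribute contract around
# xgboost. Factor predictors are one-hot encoded inside the backend (simple
# indicator columns; cardinalities here are <= 5), which keeps every split
# numeric so the attribution path can re-walk the dumped trees in double
# precision. Attributions of a factor's indicator columns are summed back to
# the original feature.

onehot_fit <- function(x) {
  is_cat <- vapply(x, function(col) is.factor(col) || is.character(col), logical(1))
  levels_of <- lapply(x[is_cat], function(col) levels(as.factor(col)))
  structure(list(columns = names(x), categorical = names(x)[is_cat],
                 levels = levels_of), class = "co2gap_onehot")
}

onehot_apply <- function(enc, x) {
  stopifnot(inherits(enc, "co2gap_onehot"))
  parts <- lapply(enc$columns, function(cn) {
    col <- x[[cn]]
    if (!cn %in% enc$categorical) {
      m <- matrix(as.numeric(col), ncol = 1)
      colnames(m) <- cn
      return(m)
    }
    lv <- enc$levels[[cn]]
    f <- factor(as.character(col), levels = lv)
    # unseen levels encode as all-zero indicators
    m <- vapply(lv, function(l) as.numeric(!is.na(f) & f == l), numeric(length(f)))
    if (!is.matrix(m)) m <- matrix(m, nrow = length(f))
    colnames(m) <- paste0(cn, "=", lv)
    m
  })
  do.call(cbind, parts)
}

onehot_origin <- function(enc) {
  out <- lapply(enc$columns, function(cn) {
    if (!cn %in% enc$categorical) return(stats::setNames(cn, cn))
    stats::setNames(rep(cn, length(enc$levels[[cn]])),
                    paste0(cn, "=", enc$levels[[cn]]))
  })
  unlist(out)
}

gbm_fit <- function(x, y, params) {
  enc <- onehot_fit(x)
  xm <- onehot_apply(enc, x)
  booster <- xgboost::xgboost(
    x = xm, y = y,
    objective = "reg:squarederror",
    max_depth = params$max_depth,
    learning_rate = params$learning_rate,
    nrounds = params$nrounds,
    reg_lambda = params$reg_lambda,
    max_bin = 64,
    nthreads = 1, seed = 0, verbosity = 0
  )
  structure(list(booster = booster, encoder = enc), class = "co2gap_gbm")
}

gbm_predict <- function(model, x) {
  stopifnot(inherits(model, "co2gap_gbm"))
  as.numeric(predict(model$booster, onehot_apply(model$encoder, x)))
}

# flatten the booster's trees into parallel arrays for the C++ kernels
forest_arrays <- function(model) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model$booster))
  dt <- dt[order(dt$Tree, dt$Node), , drop = FALSE]
  idx <- stats::setNames(seq_len(nrow(dt)) - 1L, dt$ID)
  leaf <- dt$Feature == "Leaf"
  col_names <- colnames(onehot_apply(model$encoder,
                                     empty_frame(model$encoder)))
  feat <- match(dt$Feature, col_names) - 1L
  if (any(is.na(feat) & !leaf)) {
    stop_schema("tree dump references unknown feature(s): ",
                paste(utils::head(unique(dt$Feature[is.na(feat) & !leaf]), 5),
                      collapse = ", "))
  }
  child <- function(ids) ifelse(is.na(ids), -1L, unname(idx[ids]))
  list(
    feature = as.integer(ifelse(leaf, -1L, feat)),
    threshold = as.numeric(ifelse(leaf, 0, dt$Split)),
    yes = as.integer(child(dt$Yes)),
    no = as.integer(child(dt$No)),
    missing = as.integer(child(dt$Missing)),
    value = as.numeric(ifelse(leaf, dt$Gain, 0)),
    cover = as.numeric(dt$Cover),
    tree_root = as.integer(unname(idx[paste0(unique(dt$Tree), "-0")])),
    col_names = col_names,
    base_score = gbm_base_score(model$booster)
  )
}

empty_frame <- function(enc) {
  cols <- lapply(enc$columns, function(cn) {
    if (cn %in% enc$categorical) factor(character(), levels = enc$levels[[cn]])
    else numeric()
  })
  stats::setNames(as.data.frame(cols, check.names = FALSE), enc$columns)
}

gbm_base_score <- function(booster) {
  cfg <- xgboost::xgb.config(booster)
  as.numeric(cfg$learner$learner_model_param$base_score)
}

# model output recomputed from the dumped trees in double precision
gbm_predict_double <- function(model, x) {
  fa <- forest_arrays(model)
  xm <- onehot_apply(model$encoder, x)[, fa$col_names, drop = FALSE]
  .forest_predict_cpp(xm, fa$feature, fa$threshold, fa$yes, fa$no, fa$missing,
                      fa$value, fa$cover, fa$tree_root, fa$base_score)
}

#' Double-precision TreeSHAP attributions for a boosted model
#'
#' Re-walks the fitted trees in double precision to produce exact additive
#' (SHAP) attributions: per row, the intercept column plus the per-feature
#' attributions equals the double-precision model output to floating-point
#' rounding. Indicator columns of one-hot-encoded factors are summed back to
#' the original feature.
#'
#' @param model A fitted backend model (as stored in a `co2gap_cv`).
#' @param x Data frame of rows to attribute (original feature columns).
#' @return List with `contrib` (matrix, one column per original feature plus
#'   `"(Intercept)"`) and `pred` (double-precision model output).
#' @export
gbm_attribution <- function(model, x) {
  stopifnot(inherits(model, "co2gap_gbm"))
  fa <- forest_arrays(model)
  xm <- onehot_apply(model$encoder, x)[, fa$col_names, drop = FALSE]
  phi <- .forest_treeshap_cpp(xm, fa$feature, fa$threshold, fa$yes, fa$no,
                              fa$missing, fa$value, fa$cover, fa$tree_root,
                              fa$base_score)
  colnames(phi) <- c(fa$col_names, "(Intercept)")
  origin <- c(onehot_origin(model$encoder), "(Intercept)" = "(Intercept)")
  groups <- origin[colnames(phi)]
  agg <- vapply(unique(groups), function(g) {
    rowSums(phi[, groups == g, drop = FALSE])
  }, numeric(nrow(phi)))
  if (!is.matrix(agg)) agg <- matrix(agg, nrow = nrow(phi),
                                     dimnames = list(NULL, unique(groups)))
  pred <- .forest_predict_cpp(xm, fa$feature, fa$threshold, fa$yes, fa$no,
                              fa$missing, fa$value, fa$cover, fa$tree_root,
                              fa$base_score)
  list(contrib = agg, pred = as.numeric(pred))
}
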