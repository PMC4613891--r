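# Linear QSPR models mapping EEM charge descriptors to pKa, the dissociated
# form construction they require, and Henderson-Hasselbalch ionization
# fractions. A phenol-type model reads three descriptors off the neutral
# form (the phenolic H and O and the C bearing them); carboxylic-acid models
# read the carboxyl-group charges of both the neutral and dissociated forms.

#' Construct a linear QSPR model
#'
#' pKa = intercept + sum_i coefficient_i * descriptor_i, with one
#' coefficient per named charge descriptor.
#'
#' @param descriptor_names ordered character vector, e.g.
#'   `c("q_HO4", "q_O4", "q_C4")` for phenols or
#'   `c("q_H", "q_O1", "q_O2", "q_C1", "q_O1D", "q_O2D", "q_C1D")` for
#'   carboxylic acids.
#' @param coefficients numeric, one per descriptor.
#' @param intercept numeric scalar.
#' @param name model name.
#' @param provenance free-text description of where the parameters come
#'   from.
#' @return an object of class `qspr_model`.
#' @export
qspr_model <- function(descriptor_names, coefficients, intercept,
                       name = "qspr", provenance = "") {
  if (length(descriptor_names) != length(coefficients))
    stop("coefficient count (", length(coefficients),
         ") must equal descriptor count (", length(descriptor_names), ")")
  stopifnot(is.numeric(coefficients), is.numeric(intercept),
            length(intercept) == 1L)
  structure(list(name = name,
                 descriptor_names = as.character(descriptor_names),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 provenance = provenance),
            class = "qspr_model")
}

#' @export
print.qspr_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$coefficients, x$descriptor_names),
                 collapse = " ")
  cat("qspr_model '", x$name, "': pKa = ", format(x$intercept, digits = 6),
      " ", terms, "\n", sep = "")
  invisible(x)
}

#' Load / save a QSPR model as JSON
#'
#' The on-disk form is `{name, descriptor_names, coefficients, intercept,
#' provenance}`.
#'
#' @param path file path.
#' @return [qspr_model()] (load) or `path` invisibly (save).
#' @export
load_qspr_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  qspr_model(j$descriptor_names, j$coefficients, j$intercept,
             name = if (is.null(j$name)) "qspr" else j$name,
             provenance = if (is.null(j$provenance)) "" else j$provenance)
}

#' @rdname load_qspr_model
#' @param model a [qspr_model()].
#' @export
save_qspr_model <- function(model, path) {
  stopifnot(inherits(model, "qspr_model"))
  jsonlite::write_json(model[c("name", "descriptor_names", "coefficients",
                               "intercept", "provenance")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Predict pKa from charge descriptors
#'
#' @param model a [qspr_model()].
#' @param descriptors named numeric vector (or single-row data.frame)
#'   holding every model descriptor.
#' @return predicted pKa.
#' @export
predict_pka <- function(model, descriptors) {
  stopifnot(inherits(model, "qspr_model"))
  if (is.data.frame(descriptors)) descriptors <- unlist(descriptors[1, ])
  miss <- setdiff(model$descriptor_names, names(descriptors))
  if (length(miss))
    stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  v <- as.numeric(descriptors[model$descriptor_names])
  model$intercept + sum(model$coefficients * v)
}

#' Extract charge descriptors by atom name
#'
#' Binds computed charges to descriptor names through a per-molecule name
#' map, e.g. `c(q_HO4 = "HO4", q_O4 = "O4", q_C4 = "C4")` for a phenol
#' whose phenolic hydrogen is the atom named HO4.
#'
#' @param mol the [eem_molecule()] the charges belong to.
#' @param charges a [charge_set()] for `mol`.
#' @param name_map named character vector: descriptor name -> atom name.
#' @return named numeric vector of descriptor values.
#' @export
extract_descriptors <- function(mol, charges, name_map) {
  q <- charge_values(charges)
  if (length(q) != n_atoms(mol))
    stop("dimension error: charges vs molecule")
  idx <- match(name_map, mol$atoms$name)
  if (anyNA(idx))
    stop("atom name(s) not found in molecule: ",
         paste(name_map[is.na(idx)], collapse = ", "))
  stats::setNames(q[idx], names(name_map))
}

#' Construct the dissociated form of an acid
#'
#' Removes the indicated acidic hydrogen (H or D) and decrements the
#' total molecular charge by one, e.g. turning a neutral acid into its
#' anion at total charge -1 before the dissociated-form EEM solve.
#'
#' @param mol an [eem_molecule()].
#' @param acidic_H 1-based atom index, or an atom name, of the hydrogen
#'   to remove.
#' @return an [eem_molecule()] with N-1 atoms and `total_charge - 1`.
#' @export
make_dissociated <- function(mol, acidic_H) {
  stopifnot(inherits(mol, "eem_molecule"))
  if (is.character(acidic_H)) {
    idx <- match(acidic_H, mol$atoms$name)
    if (is.na(idx)) stop("no atom named '", acidic_H, "'")
    acidic_H <- idx
  }
  if (acidic_H < 1L || acidic_H > n_atoms(mol))
    stop("atom index out of range: ", acidic_H)
  el <- mol$atoms$element[acidic_H]
  if (!(el %in% c("H", "D")))
    stop("invalid deprotonation: atom ", acidic_H, " is ", el, ", not H or D")
  out <- subset_atoms(mol, setdiff(seq_len(n_atoms(mol)), acidic_H))
  out$total_charge <- mol$total_charge - 1L
  out
}

#' Henderson-Hasselbalch ionized fraction
#'
#' Fraction of a monoprotic acid present in the ionized form at a given
#' pH: `10^(pH - pKa) / (1 + 10^(pH - pKa))`. Strictly increasing in pH,
#' exactly 0.5 at pH = pKa.
#'
#' @param pka acid dissociation constant (negative log).
#' @param ph solution pH.
#' @return fraction in \[0, 1\].
#' @export
ionized_fraction <- function(pka, ph) {
  r <- 10^(ph - pka)
  r / (1 + r)
}

descriptor_matrix <- function(descriptors) {
  if (is.data.frame(descriptors)) return(as.matrix(descriptors))
  if (is.list(descriptors)) {
    nms <- names(descriptors[[1]])
    return(do.call(rbind, lapply(descriptors, function(d) as.numeric(d[nms]))) |>
             `colnames<-`(nms))
  }
  stop("descriptors must be a data.frame or a list of named vectors")
}

#' Fit a QSPR model by multilinear regression
#'
#' Ordinary least squares of observed pKa on the charge descriptors.
#'
#' @param descriptors data.frame (rows = molecules, columns = descriptor
#'   names) or list of named vectors.
#' @param observed_pka numeric vector of experimental pKa values.
#' @param name model name for the result.
#' @return a [qspr_model()].
#' @export
fit_qspr <- function(descriptors, observed_pka, name = "qspr_fit") {
  X <- descriptor_matrix(descriptors)
  if (nrow(X) != length(observed_pka))
    stop("dimension error: ", nrow(X), " descriptor rows vs ",
         length(observed_pka), " pKa values")
  p <- ncol(X)
  if (nrow(X) < p + 1L)
    stop("need at least ", p + 1L, " molecules to fit ", p,
         " descriptors plus an intercept; got ", nrow(X))
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dep <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("collinear descriptor column(s): ", paste(dep, collapse = ", "))
  }
  fit <- stats::lm.fit(design, observed_pka)
  qspr_model(colnames(X), fit$coefficients[-1L], fit$coefficients[1L],
             name = name, provenance = "fit by ordinary least squares")
}

#' Cross-validate a QSPR fit
#'
#' Repeated random-subsampling validation as used for charge-based pKa
#' models: in each of `k` rounds, `train_size` molecules are drawn at
#' random (without replacement) to fit the model and the remainder
#' validates it. `mode = "folds"` instead partitions the data into `k`
#' disjoint folds, training on the complement of each.
#'
#' @inheritParams fit_qspr
#' @param k number of rounds (or folds).
#' @param train_size training-set size per round (ignored for
#'   `mode = "folds"`); default 35 of a 45-molecule set.
#' @param seed integer RNG seed for the draws.
#' @param mode `"subsample"` (default) or `"folds"`.
#' @return list of class `qspr_cv`: `fold_models`, per-round `mae` and
#'   `rmse` (pKa units), `mean_mae`, `mean_rmse`, and the `splits` used.
#' @export
cross_validate <- function(descriptors, observed_pka, k = 5L,
                           train_size = 35L, seed = 1L,
                           mode = c("subsample", "folds")) {
  mode <- match.arg(mode)
  X <- descriptor_matrix(descriptors)
  n <- nrow(X)
  if (n != length(observed_pka)) stop("dimension error")
  if (mode == "subsample" && n < train_size + 1L)
    stop("dataset size ", n, " leaves no validation molecules for train_size ",
         train_size)
  splits <- with_seed(seed, {
    if (mode == "subsample") {
      lapply(seq_len(k), function(i) sort(sample.int(n, train_size)))
    } else {
      fold_of <- sample(rep_len(seq_len(k), n))
      lapply(seq_len(k), function(i) which(fold_of != i))
    }
  })
  fold_models <- vector("list", k)
  mae <- rmse <- numeric(k)
  for (i in seq_len(k)) {
    tr <- splits[[i]]
    va <- setdiff(seq_len(n), tr)
    m <- fit_qspr(as.data.frame(X[tr, , drop = FALSE]), observed_pka[tr],
                  name = paste0("fold", i))
    pred <- apply(X[va, , drop = FALSE], 1L, function(row) predict_pka(m, row))
    err <- pred - observed_pka[va]
    fold_models[[i]] <- m
    mae[i] <- mean(abs(err))
    rmse[i] <- sqrt(mean(err^2))
  }
  structure(list(fold_models = fold_models, mae = mae, rmse = rmse,
                 mean_mae = mean(mae), mean_rmse = mean(rmse),
                 splits = splits, mode = mode),
            class = "qspr_cv")
}

#' @export
print.qspr_cv <- function(x, ...) {
  cat("QSPR cross-validation (", length(x$mae), " rounds, ", x$mode, "):\n",
      "  validation MAE per round: ",
      paste(sprintf("%.3f", x$mae), collapse = " "), "\n",
      "  mean MAE = ", sprintf("%.3f", x$mean_mae),
      "  mean RMSE = ", sprintf("%.3f", x$mean_rmse), " pKa units\n", sep = "")
  invisible(x)
}
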