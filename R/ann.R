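# Two-layer perceptron and automatic ensemble protocol.
#
# The classification network maps the four hypotensive predictors (ED20
# mg/kg, index, ED20 umol/kg, level) through one hidden layer to two
# output units, one per IOP class. Activation functions follow the named
# set Identity, Logistic, Tanh, Exponential, Sine for either layer plus
# Softmax for the output layer; loss is cross-entropy with a Softmax
# output and sum-of-squares otherwise. Training is full-batch BFGS
# (a quasi-Newton scheme) with analytic gradients, a small ridge penalty
# on the weights, z-score input standardization fitted on the training
# split only, and a seeded stratified 80/20 split.
#
# The automatic protocol trains `n_networks` randomly configured networks
# (hidden size, activation pair, split and initialization seeds all drawn
# from one master seed), ranks them by test accuracy (ties: train
# accuracy, then fewer hidden units, then draw order), retains the top
# `n_retain` and designates the top-ranked network as the best model.

.HIDDEN_ACTS <- c("Identity", "Logistic", "Tanh", "Exponential", "Sine")
.OUTPUT_ACTS <- c(.HIDDEN_ACTS, "Softmax")
.EXP_CLIP <- 30

.act_forward <- function(name, z) {
  switch(name,
         Identity = z,
         Logistic = 1 / (1 + exp(-z)),
         Tanh = tanh(z),
         Exponential = exp(pmin(pmax(z, -.EXP_CLIP), .EXP_CLIP)),
         Sine = sin(z),
         Softmax = {
           e <- exp(z - apply(z, 1L, max))
           e / rowSums(e)
         },
         stopf("unknown activation '%s'", name))
}

.act_deriv <- function(name, z, v) {
  switch(name,
         Identity = array(1, dim(z)),
         Logistic = v * (1 - v),
         Tanh = 1 - v^2,
         Exponential = v * (z > -.EXP_CLIP & z < .EXP_CLIP),
         Sine = cos(z),
         stopf("no elementwise derivative for activation '%s'", name))
}

.pack <- function(W1, b1, W2, b2) c(W1, b1, W2, b2)

.unpack <- function(par, d, h, o) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * o)], h, o); i <- i + h * o
  b2 <- par[i + seq_len(o)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.mlp_forward <- function(par, X, d, h, o, hidden_act, output_act) {
  w <- .unpack(par, d, h, o)
  Z1 <- sweep(X %*% w$W1, 2L, w$b1, `+`)
  H <- .act_forward(hidden_act, Z1)
  Z2 <- sweep(H %*% w$W2, 2L, w$b2, `+`)
  O <- .act_forward(output_act, Z2)
  list(w = w, Z1 = Z1, H = H, Z2 = Z2, O = O)
}

.stratified_split <- function(y, train_fraction, split_seed, max_retries = 20L) {
  n <- length(y)
  classes <- sort(unique(y))
  for (attempt in seq_len(max_retries)) {
    idx_train <- with_seed(split_seed + (attempt - 1L), {
      unlist(lapply(classes, function(cl) {
        members <- which(y == cl)
        n_tr <- max(1L, round(train_fraction * length(members)))
        n_tr <- min(n_tr, length(members))
        sort(sample(members, n_tr))
      }), use.names = FALSE)
    })
    idx_test <- setdiff(seq_len(n), idx_train)
    train_classes <- unique(y[idx_train])
    enough <- all(vapply(classes, function(cl) {
      sum(y[idx_train] == cl) >= min(2L, sum(y == cl))
    }, logical(1)))
    if (setequal(train_classes, classes) && enough) {
      return(list(train = sort(idx_train), test = idx_test))
    }
  }
  stopf("could not produce a training split containing every class after %d retries", max_retries)
}

#' Train a single two-layer perceptron classifier
#'
#' @param X numeric matrix/data frame of predictors (4 columns for the
#'   hypotensive profile: ED20 mg/kg, index, ED20 umol/kg, level).
#' @param y binary class vector (1 = IOP active, 0 = inactive).
#' @param n_hidden hidden units (the protocol samples 3-10).
#' @param hidden_activation one of Identity, Logistic, Tanh, Exponential,
#'   Sine.
#' @param output_activation as above, plus Softmax.
#' @param train_fraction fraction used for training (default 0.8); the
#'   split is stratified by class so small classes stay represented.
#' @param split_seed,init_seed seeds for the split and the weight
#'   initialization.
#' @param max_epochs BFGS iteration cap (default 300).
#' @param tol relative convergence tolerance (default 1e-8).
#' @param decay ridge penalty on the weights (default 1e-4).
#' @return an `iopqsar_mlp` model: weights, activations, standardization
#'   parameters, split indices, train/test accuracies, `converged` flag.
#' @export
train_mlp <- function(X, y, n_hidden = 5L,
                      hidden_activation = "Tanh", output_activation = "Softmax",
                      train_fraction = 0.8, split_seed = 1L, init_seed = 1L,
                      max_epochs = 300L, tol = 1e-8, decay = 1e-4) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stopf("predictor matrix contains missing/non-finite values")
  y <- .check_binary_y(y, nrow(X))
  if (!hidden_activation %in% .HIDDEN_ACTS) {
    stopf("hidden activation must be one of: %s", paste(.HIDDEN_ACTS, collapse = ", "))
  }
  if (!output_activation %in% .OUTPUT_ACTS) {
    stopf("output activation must be one of: %s", paste(.OUTPUT_ACTS, collapse = ", "))
  }
  n <- nrow(X); d <- ncol(X); h <- as.integer(n_hidden); o <- 2L
  if (h < 1L) stopf("n_hidden must be positive")

  split <- .stratified_split(y, train_fraction, split_seed)
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]

  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Xs <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, `/`)

  Ttr <- cbind(class0 = as.numeric(ytr == 0L), class1 = as.numeric(ytr == 1L))
  softmax_out <- output_activation == "Softmax"

  loss_fn <- function(par) {
    fw <- .mlp_forward(par, Xs, d, h, o, hidden_activation, output_activation)
    data_loss <- if (softmax_out) {
      -sum(Ttr * log(pmax(fw$O, 1e-12))) / nrow(Xs)
    } else {
      0.5 * sum((fw$O - Ttr)^2) / nrow(Xs)
    }
    data_loss + 0.5 * decay * (sum(fw$w$W1^2) + sum(fw$w$W2^2))
  }
  grad_fn <- function(par) {
    fw <- .mlp_forward(par, Xs, d, h, o, hidden_activation, output_activation)
    nr <- nrow(Xs)
    dZ2 <- if (softmax_out) {
      (fw$O - Ttr) / nr
    } else {
      ((fw$O - Ttr) * .act_deriv(output_activation, fw$Z2, fw$O)) / nr
    }
    dW2 <- crossprod(fw$H, dZ2) + decay * fw$w$W2
    db2 <- colSums(dZ2)
    dZ1 <- (dZ2 %*% t(fw$w$W2)) * .act_deriv(hidden_activation, fw$Z1, fw$H)
    dW1 <- crossprod(Xs, dZ1) + decay * fw$w$W1
    db1 <- colSums(dZ1)
    .pack(dW1, db1, dW2, db2)
  }

  par0 <- with_seed(init_seed, {
    c(stats::runif(d * h, -0.5, 0.5) / sqrt(d), rep(0, h),
      stats::runif(h * o, -0.5, 0.5) / sqrt(h), rep(0, o))
  })
  opt <- stats::optim(par0, loss_fn, grad_fn, method = "BFGS",
                      control = list(maxit = as.integer(max_epochs), reltol = tol))

  model <- structure(
    list(
      dim_in = d, n_hidden = h, dim_out = o,
      hidden_activation = hidden_activation, output_activation = output_activation,
      par = opt$par, mu = mu, sd = sdv,
      split_seed = split_seed, init_seed = init_seed,
      train_fraction = train_fraction, decay = decay,
      idx_train = split$train, idx_test = split$test,
      converged = opt$convergence == 0L, loss = opt$value,
      classes = c(0L, 1L)
    ),
    class = "iopqsar_mlp"
  )
  model$train_accuracy <- mean(predict(model, Xtr, type = "class") == ytr)
  model$test_accuracy <- if (length(split$test) > 0L) {
    mean(predict(model, X[split$test, , drop = FALSE], type = "class") == y[split$test])
  } else {
    NA_real_
  }
  model
}

.check_binary_y <- function(y, n) {
  y <- as.integer(y)
  if (length(y) != n) stopf("length of y (%d) must match rows of X (%d)", length(y), n)
  if (!all(y %in% c(0L, 1L))) stopf("y must be binary 0/1")
  y
}

#' Predict from a trained perceptron
#'
#' @param object an `iopqsar_mlp` model.
#' @param newdata predictor matrix with the model's input dimension.
#' @param type `"prob"` for the two output-unit values (a probability
#'   simplex when the output activation is Softmax; raw unit outputs
#'   otherwise), `"class"` for the argmax label (0/1).
#' @param ... unused.
#' @return matrix (`"prob"`) or integer vector (`"class"`).
#' @export
predict.iopqsar_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$dim_in) {
    stopf("newdata has %d columns; model expects %d", ncol(X), object$dim_in)
  }
  Xs <- sweep(sweep(X, 2L, object$mu), 2L, object$sd, `/`)
  fw <- .mlp_forward(object$par, Xs, object$dim_in, object$n_hidden, object$dim_out,
                     object$hidden_activation, object$output_activation)
  colnames(fw$O) <- c("class0", "class1")
  if (type == "prob") fw$O else as.integer(fw$O[, "class1"] >= fw$O[, "class0"])
}

#' @export
print.iopqsar_mlp <- function(x, ...) {
  cat(sprintf("<iopqsar_mlp> %d-%d-%d (%s/%s)  train acc %.3f, test acc %.3f%s\n",
              x$dim_in, x$n_hidden, x$dim_out,
              x$hidden_activation, x$output_activation,
              x$train_accuracy, x$test_accuracy,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Run the automatic ensemble protocol
#'
#' Samples `n_networks` network configurations (hidden size uniform on
#' `hidden_range`, activation pair uniform over the permitted sets, fresh
#' split and initialization seeds) from one master seed, trains each on a
#' stratified `train_fraction` split, ranks all trained networks by test
#' accuracy (ties broken by train accuracy, then by fewer hidden units,
#' then by draw order), retains the top `n_retain` and returns the
#' top-ranked network as the best model. Per-network failures are logged
#' and excluded; the run aborts if more than 10% fail.
#'
#' @inheritParams train_mlp
#' @param n_networks networks to train (protocol default 1000).
#' @param n_retain networks to keep (protocol default 50).
#' @param hidden_range integer range of hidden units, default `c(3, 10)`.
#' @param hidden_activations,output_activations candidate activation sets.
#' @param master_seed seed governing every random choice of the run.
#' @return an `iopqsar_ensemble`: `summary` data frame (one row per
#'   trained network with rank), `retained` (indices of the kept top
#'   networks), `best_model` (`iopqsar_mlp`), `best_index`, `failed`
#'   (indices of failed draws), and the call configuration.
#' @export
run_ensemble <- function(X, y, n_networks = 1000L, n_retain = 50L,
                         hidden_range = c(3L, 10L),
                         hidden_activations = .HIDDEN_ACTS,
                         output_activations = .OUTPUT_ACTS,
                         master_seed, train_fraction = 0.8,
                         max_epochs = 100L, tol = 1e-6, decay = 1e-4) {
  if (missing(master_seed)) stopf("`master_seed` is required")
  X <- as.matrix(X)
  y <- .check_binary_y(y, nrow(X))
  stopifnot(length(hidden_range) == 2L, hidden_range[1] >= 1L,
            hidden_range[2] >= hidden_range[1])
  if (!all(hidden_activations %in% .HIDDEN_ACTS)) stopf("invalid hidden activation set")
  if (!all(output_activations %in% .OUTPUT_ACTS)) stopf("invalid output activation set")

  cfg <- with_seed(master_seed, {
    data.frame(
      n_hidden = sample(seq(hidden_range[1], hidden_range[2]), n_networks, replace = TRUE),
      hidden_activation = sample(hidden_activations, n_networks, replace = TRUE),
      output_activation = sample(output_activations, n_networks, replace = TRUE),
      split_seed = sample.int(.Machine$integer.max - 21L, n_networks),
      init_seed = sample.int(.Machine$integer.max - 1L, n_networks),
      stringsAsFactors = FALSE
    )
  })

  models <- vector("list", n_networks)
  train_acc <- test_acc <- rep(NA_real_, n_networks)
  converged <- rep(NA, n_networks)
  failed <- character(n_networks)
  for (i in seq_len(n_networks)) {
    res <- tryCatch(
      train_mlp(X, y, n_hidden = cfg$n_hidden[i],
                hidden_activation = cfg$hidden_activation[i],
                output_activation = cfg$output_activation[i],
                train_fraction = train_fraction,
                split_seed = cfg$split_seed[i], init_seed = cfg$init_seed[i],
                max_epochs = max_epochs, tol = tol, decay = decay),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed[i] <- conditionMessage(res)
    } else {
      models[[i]] <- res
      train_acc[i] <- res$train_accuracy
      test_acc[i] <- res$test_accuracy
      converged[i] <- res$converged
    }
  }
  fail_idx <- which(nzchar(failed))
  if (length(fail_idx) > n_networks * 0.1) {
    stopf("ensemble aborted: %d of %d networks failed to train", length(fail_idx), n_networks)
  }

  summary_df <- cbind(index = seq_len(n_networks), cfg,
                      train_accuracy = train_acc, test_accuracy = test_acc,
                      converged = converged)
  ok <- which(!is.na(test_acc))
  ord <- ok[order(-test_acc[ok], -train_acc[ok], cfg$n_hidden[ok], ok, method = "radix")]
  rank <- rep(NA_integer_, n_networks)
  rank[ord] <- seq_along(ord)
  summary_df$rank <- rank
  retained <- ord[seq_len(min(n_retain, length(ord)))]

  structure(
    list(summary = summary_df,
         retained = retained,
         best_index = ord[1L],
         best_model = models[[ord[1L]]],
         retained_models = models[retained],
         failed = fail_idx,
         n_networks = n_networks, n_retain = n_retain,
         hidden_range = hidden_range, master_seed = master_seed,
         train_fraction = train_fraction),
    class = "iopqsar_ensemble"
  )
}

#' @export
print.iopqsar_ensemble <- function(x, ...) {
  cat(sprintf("<iopqsar_ensemble> %d trained (%d failed), %d retained; master seed %s\n",
              x$n_networks, length(x$failed), length(x$retained),
              format(x$master_seed)))
  cat("best: "); print(x$best_model)
  invisible(x)
}
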