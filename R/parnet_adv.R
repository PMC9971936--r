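#' Model configuration for the shallow parallel classifier
#'
#' The classifier is a "non-deep" three-stream convolutional network of
#' fixed depth 12 (parameterized layers on the longest input-to-output
#' path, counting a factorized 1x7/7x1 pair as one convolutional layer
#' since it substitutes a single 3x3). Each stream processes the input at a
#' different spatial scale; stream blocks combine a pointwise 1x1 branch, a
#' factorized 1x7-then-7x1 branch (or a plain 3x3 when
#' `kernel_mode = "square_3x3"`) and a squeeze-excitation skip gate, fused
#' by addition, batch-normalized and passed through SiLU. Fusion blocks
#' merge streams by concatenation plus a 1x1 convolution; the head is a
#' global average pool and a fully connected layer over the two rhythm
#' classes.
#'
#' @param input_size square input side in pixels (default 299).
#' @param in_channels input channels; 3 per stacked lead.
#' @param stream_widths channel widths of the three streams (default
#'   16/32/64, a desk-scale profile; widths are freely configurable).
#' @param kernel_mode `"asymmetric_1x7_7x1"` (default) or `"square_3x3"`.
#' @param factor_order order of the factorized pair, `"1x7_first"`
#'   (default) or `"7x1_first"`.
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 64).
#' @param epochs training epochs.
#' @param n_classes number of output classes (2).
#' @param classes class labels in output-column order.
#' @param seed integer seed for weight initialization and shuffling.
#' @return a list of class `model_config`.
#' @export
model_config <- function(input_size = 299L, in_channels = 3L,
                         stream_widths = c(16L, 32L, 64L),
                         kernel_mode = c("asymmetric_1x7_7x1", "square_3x3"),
                         factor_order = c("1x7_first", "7x1_first"),
                         lr = 0.001, batch_size = 64L, epochs = 10L,
                         n_classes = 2L, classes = c("AF", "NSR"),
                         seed = 1L) {
  kernel_mode <- match.arg(kernel_mode)
  factor_order <- match.arg(factor_order)
  stopifnot(length(stream_widths) == 3, all(stream_widths >= 1),
            input_size >= 16, in_channels >= 1, lr > 0, batch_size >= 1,
            n_classes == length(classes))
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 stream_widths = as.integer(stream_widths),
                 kernel_mode = kernel_mode, factor_order = factor_order,
                 n_streams = 3L, activation = "SiLU", loss = "cross-entropy",
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), n_classes = as.integer(n_classes),
                 classes = classes, seed = as.integer(seed)),
            class = "model_config")
}

#' Preset model profiles
#'
#' `"paper"`: 299x299 inputs with wider streams (the configuration scale
#' used for clinical-database training). `"desk"`: 64x64 inputs, widths
#' 16/32/64, sized so that a full training run takes minutes on one CPU.
#' `"fast"`: 24x24 inputs with narrow streams and a larger learning rate,
#' used where many models must be fitted (e.g. inside the stepwise lead
#' search).
#'
#' @param profile one of `"paper"`, `"desk"`, `"fast"`.
#' @param ... overrides forwarded to [model_config()].
#' @return a `model_config`.
#' @export
parnet_profile <- function(profile = c("desk", "fast", "paper"), ...) {
  profile <- match.arg(profile)
  args <- switch(profile,
    paper = list(input_size = 299L, stream_widths = c(64L, 128L, 256L),
                 batch_size = 64L, lr = 0.001, epochs = 30L),
    desk = list(input_size = 64L, stream_widths = c(16L, 32L, 64L),
                batch_size = 32L, lr = 0.001, epochs = 6L),
    fast = list(input_size = 24L, stream_widths = c(8L, 16L, 32L),
                batch_size = 32L, lr = 0.01, epochs = 12L))
  utils::modifyList(do.call(model_config, args), list(...))
}

make_block <- function(width, cfg) {
  blk <- list(type = "block", width = width,
              p1 = conv_init(1L, 1L, width, width),
              se = se_init(width), bn = bn_init(width))
  if (cfg$kernel_mode == "asymmetric_1x7_7x1") {
    if (cfg$factor_order == "1x7_first") {
      blk$kA <- conv_init(1L, 7L, width, width)
      blk$kB <- conv_init(7L, 1L, width, width)
    } else {
      blk$kA <- conv_init(7L, 1L, width, width)
      blk$kB <- conv_init(1L, 7L, width, width)
    }
  } else {
    blk$kk <- conv_init(3L, 3L, width, width)
  }
  blk
}

make_convnode <- function(kh, kw, cin, cout, stride) {
  list(type = "conv", conv = conv_init(kh, kw, cin, cout, stride),
       bn = bn_init(cout))
}

# architecture graph: named nodes in topological order, each with the ids
# of its inputs ("in" denotes the network input)
build_graph <- function(cfg) {
  w <- cfg$stream_widths
  nodes <- list()
  add <- function(id, node, inputs) {
    node$id <- id
    node$inputs <- inputs
    nodes[[id]] <<- node
  }
  add("d1", make_convnode(3L, 3L, cfg$in_channels, w[1], 2L), "in")
  add("d2", make_convnode(3L, 3L, w[1], w[1], 2L), "d1")
  prev <- "d2"
  for (i in 1:4) {
    id <- paste0("s1b", i)
    add(id, make_block(w[1], cfg), prev)
    prev <- id
  }
  add("d3", make_convnode(3L, 3L, w[1], w[2], 2L), "d2")
  prev <- "d3"
  for (i in 1:4) {
    id <- paste0("s2b", i)
    add(id, make_block(w[2], cfg), prev)
    prev <- id
  }
  add("d4", make_convnode(3L, 3L, w[2], w[3], 2L), "d3")
  prev <- "d4"
  for (i in 1:4) {
    id <- paste0("s3b", i)
    add(id, make_block(w[3], cfg), prev)
    prev <- id
  }
  add("f1down", make_convnode(3L, 3L, w[1], w[2], 2L), "s1b4")
  add("f1cat", list(type = "concat"), c("f1down", "s2b4"))
  add("f1merge", make_convnode(1L, 1L, 2L * w[2], w[2], 1L), "f1cat")
  add("f2down", make_convnode(3L, 3L, w[2], w[3], 2L), "f1merge")
  add("f2cat", list(type = "concat"), c("f2down", "s3b4"))
  add("f2merge", make_convnode(1L, 1L, 2L * w[3], w[3], 1L), "f2cat")
  add("d5", make_convnode(3L, 3L, w[3], w[3], 2L), "f2merge")
  add("head", list(type = "head",
                   fc = list(Wm = matrix(stats::rnorm(cfg$n_classes * w[3],
                                                      0, sqrt(2 / w[3])),
                                         cfg$n_classes, w[3]),
                             b = numeric(cfg$n_classes))), "d5")
  nodes
}

#' Build an (untrained) shallow parallel classifier
#'
#' Weight initialization is seeded from `cfg$seed`, so construction is
#' deterministic.
#'
#' @param cfg a [model_config()].
#' @return object of class `parnet_model` with fields `cfg`, `nodes`,
#'   `history`, `trained`.
#' @export
build_model <- function(cfg = model_config()) {
  nodes <- with_seed(cfg$seed, function() build_graph(cfg))
  structure(list(cfg = cfg, nodes = nodes, opt = list(state = NULL, t = 0L),
                 history = NULL, trained = FALSE),
            class = "parnet_model")
}

#' Measured depth of a model
#'
#' Counts parameterized layers (convolutions -- a factorized 1x7/7x1 pair
#' counting as one -- stream blocks, and the fully connected head) along
#' the longest input-to-output path of the architecture graph. The value
#' is computed from the graph, not stored, and is 12 in both kernel modes
#' for any stream widths.
#'
#' @param model a `parnet_model`.
#' @return integer depth.
#' @export
model_depth <- function(model) {
  nodes <- model$nodes
  cost <- function(node) {
    switch(node$type, conv = 1L, block = 1L, head = 1L, concat = 0L)
  }
  depth <- c("in" = 0L)
  for (id in names(nodes)) {
    node <- nodes[[id]]
    depth[id] <- max(depth[node$inputs]) + cost(node)
  }
  unname(depth[length(depth)])
}

#' Number of parallel streams in a model
#' @param model a `parnet_model`.
#' @return integer (3).
#' @export
model_n_streams <- function(model) {
  streams <- unique(sub("b[0-9]+$", "", grep("^s[0-9]+b",
                                             names(model$nodes), value = TRUE)))
  length(streams)
}

#' Total trainable parameter count
#' @param model a `parnet_model`.
#' @return integer number of scalar parameters.
#' @export
n_parameters <- function(model) {
  total <- 0
  walk <- function(x, nm) {
    if (is.list(x)) {
      for (k in names(x)) walk(x[[k]], k)
    } else if (is.numeric(x) &&
               nm %in% c("Wm", "b", "V", "gamma", "beta")) {
      total <<- total + length(x)
    }
  }
  for (node in model$nodes) walk(node, "")
  as.integer(total)
}

node_fwd <- function(node, x, training) {
  if (node$type == "conv") {
    cv <- conv_fwd(x, node$conv)
    bn <- bn_fwd(cv$y, node$bn, training)
    ac <- silu_fwd(bn$y)
    list(y = ac$y, bn = bn$bn,
         cache = list(conv = cv$cache, bn = bn$cache, silu = ac$cache))
  } else if (node$type == "block") {
    p1 <- conv_fwd(x, node$p1)
    if (!is.null(node$kk)) {
      km <- conv_fwd(x, node$kk)
      ksum <- km$y
      kcache <- list(kk = km$cache)
    } else {
      ka <- conv_fwd(x, node$kA)
      kb <- conv_fwd(ka$y, node$kB)
      ksum <- kb$y
      kcache <- list(kA = ka$cache, kB = kb$cache)
    }
    se <- se_fwd(x, node$se)
    z <- p1$y + ksum + se$y
    bn <- bn_fwd(z, node$bn, training)
    ac <- silu_fwd(bn$y)
    list(y = ac$y, bn = bn$bn,
         cache = c(list(p1 = p1$cache, se = se$cache, x = x,
                        bn = bn$cache, silu = ac$cache), kcache))
  } else if (node$type == "concat") {
    a <- x[[1]]
    b <- x[[2]]
    da <- dim(a)
    db <- dim(b)
    stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
    y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
    y[, , seq_len(da[3]), ] <- a
    y[, , da[3] + seq_len(db[3]), ] <- b
    list(y = y, cache = list(ca = da[3], cb = db[3]))
  } else if (node$type == "head") {
    g <- gap_fwd(x)
    scores <- node$fc$Wm %*% g + node$fc$b
    list(y = scores, cache = list(g = g, d = dim(x)))
  }
}

node_bwd <- function(node, dy, cache) {
  if (node$type == "conv") {
    dz <- silu_bwd(dy, cache$silu)
    bb <- bn_bwd(dz, node$bn, cache$bn)
    cb <- conv_bwd(bb$dx, node$conv, cache$conv)
    list(dx = cb$dx,
         grads = list(conv = list(Wm = cb$dWm, b = cb$db),
                      bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
  } else if (node$type == "block") {
    dz <- silu_bwd(dy, cache$silu)
    bb <- bn_bwd(dz, node$bn, cache$bn)
    dzin <- bb$dx
    g <- list(bn = list(gamma = bb$dgamma, beta = bb$dbeta))
    p1b <- conv_bwd(dzin, node$p1, cache$p1)
    g$p1 <- list(Wm = p1b$dWm, b = p1b$db)
    dx <- p1b$dx
    if (!is.null(node$kk)) {
      kb <- conv_bwd(dzin, node$kk, cache$kk)
      g$kk <- list(Wm = kb$dWm, b = kb$db)
      dx <- dx + kb$dx
    } else {
      kbb <- conv_bwd(dzin, node$kB, cache$kB)
      kab <- conv_bwd(kbb$dx, node$kA, cache$kA)
      g$kB <- list(Wm = kbb$dWm, b = kbb$db)
      g$kA <- list(Wm = kab$dWm, b = kab$db)
      dx <- dx + kab$dx
    }
    sb <- se_bwd(dzin, cache$x, node$se, cache$se)
    g$se <- list(V = sb$dV, b = sb$db)
    dx <- dx + sb$dx
    list(dx = dx, grads = g)
  } else if (node$type == "concat") {
    list(dx = list(dy[, , seq_len(cache$ca), , drop = FALSE],
                   dy[, , cache$ca + seq_len(cache$cb), , drop = FALSE]),
         grads = NULL)
  } else if (node$type == "head") {
    dW <- dy %*% t(cache$g)
    db <- rowSums(dy)
    dg <- crossprod(node$fc$Wm, dy)
    list(dx = gap_bwd(dg, cache$d),
         grads = list(fc = list(Wm = dW, b = db)))
  }
}

forward_graph <- function(model, x, training = FALSE, keep_cache = FALSE) {
  outs <- list("in" = x)
  caches <- if (keep_cache) list() else NULL
  nodes <- model$nodes
  for (id in names(nodes)) {
    node <- nodes[[id]]
    inp <- if (node$type == "concat") outs[node$inputs] else outs[[node$inputs]]
    res <- node_fwd(node, inp, training)
    outs[[id]] <- res$y
    if (!is.null(res$bn)) model$nodes[[id]]$bn <- res$bn
    if (keep_cache) caches[[id]] <- res$cache
  }
  list(scores = outs[["head"]], outs = if (keep_cache) outs else NULL,
       caches = caches, model = model)
}

backward_graph <- function(model, caches, dscores) {
  nodes <- model$nodes
  douts <- list(head = dscores)
  grads <- list()
  for (id in rev(names(nodes))) {
    node <- nodes[[id]]
    dy <- douts[[id]]
    if (is.null(dy)) next
    res <- node_bwd(node, dy, caches[[id]])
    grads[[id]] <- res$grads
    ins <- node$inputs
    if (node$type == "concat") {
      for (j in seq_along(ins)) {
        douts[[ins[j]]] <- if (is.null(douts[[ins[j]]])) res$dx[[j]] else
          douts[[ins[j]]] + res$dx[[j]]
      }
    } else if (ins != "in") {
      douts[[ins]] <- if (is.null(douts[[ins]])) res$dx else
        douts[[ins]] + res$dx
    }
    douts[[id]] <- NULL  # free
  }
  grads
}

label_index <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) stop("labels outside model classes: ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

#' Train the classifier
#'
#' Minibatch Adam on the softmax cross-entropy loss. Shuffling and (if the
#' model is freshly built) weight initialization are controlled by the
#' model seed, so two runs from the same seed produce identical parameter
#' trajectories.
#'
#' @param model a `parnet_model` from [build_model()].
#' @param images numeric array `(H, W, C, N)` of inputs in `[0, 1]`, or a
#'   list of per-sample `(H, W, C)` arrays / `rp_image`s.
#' @param labels character vector of class labels, length N.
#' @param epochs,batch_size,lr optional overrides of the model config.
#' @param verbose print per-epoch loss.
#' @return the trained `parnet_model`, with a `history` data frame of
#'   per-epoch mean loss and training accuracy.
#' @export
train_model <- function(model, images, labels, epochs = NULL,
                        batch_size = NULL, lr = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "parnet_model"))
  x <- as_input_array(images)
  cfg <- model$cfg
  epochs <- if (is.null(epochs)) cfg$epochs else epochs
  batch_size <- if (is.null(batch_size)) cfg$batch_size else batch_size
  lr <- if (is.null(lr)) cfg$lr else lr
  n <- dim(x)[4]
  if (n == 0) stop("empty training set")
  if (length(labels) != n) stop("labels length does not match image count")
  if (dim(x)[1] != cfg$input_size || dim(x)[3] != cfg$in_channels) {
    stop(sprintf("input shape %dx%dx%d does not match config %dx%dx%d",
                 dim(x)[1], dim(x)[2], dim(x)[3],
                 cfg$input_size, cfg$input_size, cfg$in_channels))
  }
  yidx <- label_index(labels, cfg$classes)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0))
  model <- with_seed(cfg$seed + 1000L, function() {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_hits <- 0
      starts <- seq(1, n, by = batch_size)
      for (b in starts) {
        idx <- ord[b:min(b + batch_size - 1, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- forward_graph(model, xb, training = TRUE, keep_cache = TRUE)
        model <- fw$model
        ce <- softmax_ce(fw$scores, yidx[idx])
        grads <- backward_graph(model, fw$caches, ce$dscores)
        model$opt$t <- model$opt$t + 1L
        upd <- adam_step(model$nodes, grads, model$opt$state, lr,
                         model$opt$t)
        model$nodes <- upd$params
        model$opt$state <- upd$state
        ep_loss <- ep_loss + ce$loss * length(idx)
        ep_hits <- ep_hits +
          sum(apply(ce$probs, 2, which.max) == yidx[idx])
      }
      hist <<- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                      acc = ep_hits / n))
      if (verbose) {
        message(sprintf("epoch %d  loss %.4f  acc %.3f", ep,
                        ep_loss / n, ep_hits / n))
      }
    }
    model
  })
  model <- recalibrate_bn(model, x, batch_size)
  model$history <- hist
  model$trained <- TRUE
  model
}

# replace the momentum-lagged running batch-norm statistics with exact
# moments of the (final-weights) activations over the training set,
# accumulated batch-wise; removes the eval/train mismatch left by short
# training runs
recalibrate_bn <- function(model, x, batch_size = 64L) {
  n <- dim(x)[4]
  bn_ids <- names(model$nodes)[vapply(model$nodes, function(nd)
    !is.null(nd$bn), logical(1))]
  acc_mean <- list()
  acc_var <- list()
  probe <- model
  for (id in bn_ids) probe$nodes[[id]]$bn$momentum <- 0
  wtot <- 0
  for (b in seq(1, n, by = batch_size)) {
    idx <- b:min(b + batch_size - 1, n)
    fw <- forward_graph(probe, x[, , , idx, drop = FALSE], training = TRUE)
    w <- length(idx)
    for (id in bn_ids) {
      bn <- fw$model$nodes[[id]]$bn
      acc_mean[[id]] <- if (is.null(acc_mean[[id]])) w * bn$rmean else
        acc_mean[[id]] + w * bn$rmean
      acc_var[[id]] <- if (is.null(acc_var[[id]])) w * bn$rvar else
        acc_var[[id]] + w * bn$rvar
    }
    wtot <- wtot + w
  }
  for (id in bn_ids) {
    model$nodes[[id]]$bn$rmean <- acc_mean[[id]] / wtot
    model$nodes[[id]]$bn$rvar <- acc_var[[id]] / wtot
  }
  model
}

#' Class probabilities for a batch of images
#'
#' Runs the network in evaluation mode (batch statistics frozen at their
#' running values), so predictions are independent of how the batch is
#' partitioned.
#'
#' @param model a trained `parnet_model`.
#' @param images array `(H, W, C, N)` or list of per-sample arrays.
#' @param batch_size evaluation batch size.
#' @return numeric matrix `N x n_classes` of probabilities; columns named
#'   by class, rows sum to 1.
#' @export
predict_model <- function(model, images, batch_size = 64L) {
  x <- as_input_array(images)
  n <- dim(x)[4]
  out <- matrix(NA_real_, n, model$cfg$n_classes,
                dimnames = list(NULL, model$cfg$classes))
  for (b in seq(1, n, by = batch_size)) {
    idx <- b:min(b + batch_size - 1, n)
    fw <- forward_graph(model, x[, , , idx, drop = FALSE], training = FALSE)
    out[idx, ] <- t(softmax_probs(fw$scores))
  }
  out
}

#' Predicted class labels
#' @inheritParams predict_model
#' @return character vector of length N.
#' @export
predict_labels <- function(model, images, batch_size = 64L) {
  p <- predict_model(model, images, batch_size)
  colnames(p)[apply(p, 1, which.max)]
}

#' Stack per-lead recurrence images into one multi-channel input
#'
#' Channel-axis concatenation: k leads of `size x size x 3` images become
#' one `size x size x 3k` input, which is how multi-lead subsets are fed to
#' the single classifier.
#'
#' @param images_per_lead list of `rp_image`s (or `(H, W, 3)` arrays), one
#'   per lead, all the same size.
#' @return numeric array `(H, W, 3k)`.
#' @export
stack_leads <- function(images_per_lead) {
  arrs <- lapply(images_per_lead, function(im) {
    if (inherits(im, "rp_image")) im$pixels else im
  })
  d1 <- dim(arrs[[1]])
  for (a in arrs) {
    if (!all(dim(a)[1:2] == d1[1:2])) stop("lead images differ in size")
  }
  chans <- vapply(arrs, function(a) dim(a)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(chans)))
  at <- 0L
  for (a in arrs) {
    out[, , at + seq_len(dim(a)[3])] <- a
    at <- at + dim(a)[3]
  }
  out
}

# accept (H,W,C,N) array, a single (H,W,C) array, or a list of per-sample
# (H,W,C) arrays / rp_images, and return (H,W,C,N)
as_input_array <- function(images) {
  if (is.list(images) && !is.array(images)) {
    arrs <- lapply(images, function(im) {
      if (inherits(im, "rp_image")) im$pixels else im
    })
    d <- dim(arrs[[1]])
    out <- array(0, c(d, length(arrs)))
    for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
    return(out)
  }
  if (inherits(images, "rp_image")) images <- images$pixels
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  stopifnot(length(dim(images)) == 4)
  images
}

#' Save / load a model checkpoint
#'
#' Weights go to an RDS file and the configuration to a human-readable
#' JSON sidecar next to it.
#'
#' @param model a `parnet_model`.
#' @param path checkpoint path (`.rds`).
#' @return `path` (save) or the restored `parnet_model` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfgj <- sub("\\.rds$", ".json", path)
  if (cfgj == path) cfgj <- paste0(path, ".json")
  jsonlite::write_json(unclass(model$cfg), cfgj, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "parnet_model"))
  model
}

#' @export
print.parnet_model <- function(x, ...) {
  cat(sprintf(paste0("<parnet_model> depth %d, %d streams (widths %s), ",
                     "kernels %s, input %dx%dx%d, %s params, %s\n"),
              model_depth(x), model_n_streams(x),
              paste(x$cfg$stream_widths, collapse = "/"),
              x$cfg$kernel_mode, x$cfg$input_size, x$cfg$input_size,
              x$cfg$in_channels, format(n_parameters(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}
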