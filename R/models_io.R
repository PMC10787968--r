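# Model serialization: a documented JSON bundle. Numeric tensors are stored
# as base64-encoded little-endian float64 so round-trips are bit-exact; the
# SVM's libsvm internals are stored as a base64 R serialization (documented
# as such in the bundle).

enc_tensor <- function(x) {
  list(
    dim = if (is.matrix(x)) dim(x) else length(x),
    data = jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8, endian = "little"))
  )
}

dec_tensor <- function(t) {
  v <- readBin(jsonlite::base64_dec(t$data), numeric(),
    n = prod(unlist(t$dim)), size = 8, endian = "little"
  )
  d <- unlist(t$dim)
  if (length(d) == 2L) matrix(v, d[1], d[2]) else v
}

#' Export / load a trained model
#'
#' Models serialize to a single JSON bundle holding the class list, PCA
#' projector, hyperparameters and parameter tensors (base64 float64,
#' bit-exact). Loading reconstructs a model whose predictions equal the
#' original's exactly on any input.
#'
#' @param model A trained `emg_model`.
#' @param path Output path (conventionally `.json`).
#' @return `export_model()` returns `path` invisibly; `load_model()` the
#'   reconstructed model.
#' @export
export_model <- function(model, path) {
  stopifnot(inherits(model, "emg_model"))
  bundle <- list(
    format = "hdemg-model",
    version = 1L,
    kind = model$kind,
    classes = model$classes
  )
  if (!is.null(model$pca)) {
    bundle$pca <- list(
      mean = enc_tensor(model$pca$mean),
      rotation = enc_tensor(model$pca$rotation),
      explained = model$pca$explained,
      n_components = model$pca$n_components
    )
  }
  bundle$hyper <- model$hyper
  if (model$kind == "LR") {
    bundle$coef <- enc_tensor(model$coef)
  } else if (model$kind == "SVM") {
    bundle$svm_serialized <- jsonlite::base64_enc(serialize(model$svm, NULL))
  } else if (model$kind == "MLP") {
    bundle$spec <- unclass(model$spec)
    bundle$layers <- lapply(model$par$layers, function(l) {
      list(W = enc_tensor(l$W), b = enc_tensor(l$b))
    })
    bundle$bn <- lapply(model$par$bn, function(b) {
      lapply(b, enc_tensor)
    })
  }
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_model
#' @export
load_model <- function(path) {
  bundle <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      abort(sprintf("Not a readable model bundle (%s): %s", path, conditionMessage(e)))
    }
  )
  if (!identical(bundle$format, "hdemg-model")) {
    abort(sprintf("File %s is not an hdemg model bundle.", path))
  }
  classes <- unlist(bundle$classes)
  pca <- if (!is.null(bundle$pca)) {
    list(
      mean = dec_tensor(bundle$pca$mean),
      rotation = dec_tensor(bundle$pca$rotation),
      explained = bundle$pca$explained,
      n_components = bundle$pca$n_components
    )
  }
  kind <- bundle$kind
  if (kind == "LR") {
    structure(
      list(
        kind = "LR", classes = classes, pca = pca,
        coef = dec_tensor(bundle$coef), hyper = bundle$hyper, cv = NULL
      ),
      class = c("emg_lr", "emg_model")
    )
  } else if (kind == "SVM") {
    structure(
      list(
        kind = "SVM", classes = classes, pca = pca,
        svm = unserialize(jsonlite::base64_dec(bundle$svm_serialized)),
        hyper = bundle$hyper, cv = NULL
      ),
      class = c("emg_svm", "emg_model")
    )
  } else if (kind == "MLP") {
    spec <- bundle$spec
    spec <- mlp_spec(
      input_dim = spec$input_dim,
      hidden = unlist(spec$hidden),
      n_classes = spec$n_classes, dropout = spec$dropout,
      smoothing = spec$smoothing, epochs = spec$epochs,
      batch_size = spec$batch_size, max_lr = spec$max_lr,
      val_frac = spec$val_frac, patience = spec$patience
    )
    par <- list(
      layers = lapply(bundle$layers, function(l) {
        list(W = dec_tensor(l$W), b = dec_tensor(l$b))
      }),
      bn = lapply(bundle$bn, function(b) lapply(b, dec_tensor))
    )
    structure(
      list(
        kind = "MLP", classes = classes, pca = NULL,
        par = par, spec = spec, hyper = bundle$hyper,
        log = NULL
      ),
      class = c("emg_mlp", "emg_model")
    )
  } else {
    abort(sprintf("Unknown model kind '%s' in bundle.", kind))
  }
}
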