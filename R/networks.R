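#' Generator configuration
#'
#' Describes the U-Net translator: an encoder of `depth` stride-2
#' down-convolutions and a decoder of `depth` up-convolutions with skip
#' connections. With `use_style = TRUE` every decoder block becomes a style
#' block: a 3x3 convolution whose kernel is rescaled per input channel by a
#' learned function of a style vector produced from a standard-normal latent
#' by a mapping network, enabling one-to-many generation from a single
#' sketch.
#'
#' @param image_size Input/output side length in pixels (default 128).
#' @param depth Number of down/up-sampling stages; `image_size` must be
#'   divisible by `2^depth` (default 7, giving a 1x1 bottleneck at 128).
#' @param base_channels Channels of the first encoder stage; subsequent
#'   stages double up to a cap of `8 * base_channels` (default 64).
#' @param use_style Build the style-modulated decoder instead of plain
#'   up-convolutions.
#' @param latent_dim Length of the latent/style vectors (default 512).
#' @param demodulate Rescale each modulated kernel to unit output variance
#'   (StyleGAN2-style weight demodulation); switchable for ablation.
#' @return A list of class `sk_gen_config`.
#' @export
generator_config <- function(image_size = 128L, depth = 7L, base_channels = 64L,
                             use_style = FALSE, latent_dim = 512L,
                             demodulate = TRUE) {
  image_size <- as.integer(image_size); depth <- as.integer(depth)
  if (latent_dim < 1L) stop("latent_dim must be positive")
  if (image_size %% (2L^depth) != 0L)
    stop("image_size must be divisible by 2^depth")
  structure(list(image_size = image_size, depth = depth,
                 base_channels = as.integer(base_channels),
                 use_style = isTRUE(use_style),
                 latent_dim = as.integer(latent_dim),
                 demodulate = isTRUE(demodulate)),
            class = "sk_gen_config")
}

enc_channels <- function(cfg) {
  pmin(cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L), cfg$base_channels * 8L)
}

winit <- function(...) array(stats::rnorm(prod(c(...)), sd = 0.02), dim = c(...))

pget <- function(model, name, grad) {
  p <- model$params[[name]]
  if (is.null(p)) stop("unknown parameter: ", name)
  if (grad) p else p$value
}

#' Build the baseline pix2pix generator
#'
#' U-Net translator mapping a binary sketch to a lung-window CT image.
#' The encoder applies `depth` 4x4 stride-2 convolutions
#' (leaky-ReLU 0.2, instance norm except at the first stage and the 1x1
#' bottleneck); the decoder applies `depth` 4x4 stride-2 transposed
#' convolutions (ReLU, instance norm), each skip-connected to the encoder
#' stage of matching resolution, ending in a 1-channel tanh output.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A model object (list with `params`, `config`, `type`).
#' @export
build_generator <- function(config = generator_config(), seed = 0L) {
  if (!inherits(config, "sk_gen_config")) stop("config must be a generator_config")
  model <- new.env(parent = emptyenv())
  model$params <- list()
  model$config <- config
  model$type <- if (config$use_style) "stylepix2pix_g" else "pix2pix_g"
  ch <- enc_channels(config); d <- config$depth
  local_seed(seed, {
    cin <- 1L
    for (i in seq_len(d)) {
      model$params[[paste0("enc", i, "_W")]] <- ag_leaf(winit(4L, 4L, cin, ch[i]))
      model$params[[paste0("enc", i, "_b")]] <- ag_leaf(numeric(ch[i]))
      cin <- ch[i]
    }
    # decoder block i upsamples from resolution 2^(i-1) to 2^i
    for (i in seq_len(d)) {
      cin_i <- if (i == 1L) ch[d] else 2L * ch[d - i + 1L]
      cout_i <- if (i == d) 1L else ch[d - i]
      if (config$use_style) {
        model$params[[paste0("dec", i, "_W")]] <- ag_leaf(winit(3L, 3L, cin_i, cout_i))
      } else {
        model$params[[paste0("dec", i, "_W")]] <- ag_leaf(winit(4L, 4L, cout_i, cin_i))
      }
      model$params[[paste0("dec", i, "_b")]] <- ag_leaf(numeric(cout_i))
    }
    if (config$use_style) {
      L <- config$latent_dim
      for (j in 1:4) {
        model$params[[paste0("map_fc", j, "_W")]] <- ag_leaf(winit(L, L) * 5)
        model$params[[paste0("map_fc", j, "_b")]] <- ag_leaf(numeric(L))
      }
      for (i in seq_len(d)) {
        cin_i <- if (i == 1L) ch[d] else 2L * ch[d - i + 1L]
        for (j in 1:3) {
          model$params[[paste0("sty", i, "_fc", j, "_W")]] <- ag_leaf(winit(L, L) * 5)
          model$params[[paste0("sty", i, "_fc", j, "_b")]] <- ag_leaf(numeric(L))
        }
        model$params[[paste0("sty", i, "_fc4_W")]] <- ag_leaf(winit(cin_i, L))
        model$params[[paste0("sty", i, "_fc4_b")]] <- ag_leaf(rep(1, cin_i))
      }
    }
  })
  class(model) <- c("sk_generator", "sk_model")
  model
}

#' Build the style-modulated generator
#'
#' Same U-Net topology as [build_generator()], with every decoder
#' up-convolution replaced by a style block (nearest x2 upsampling followed
#' by a style-modulated 3x3 convolution), a shared 4-layer fully connected
#' mapping network turning a standard-normal latent into a style vector, and
#' per-block 4-layer fully connected style heads emitting per-input-channel
#' kernel scales.
#'
#' @inheritParams build_generator
#' @return A model object; its forward signature is (sketch, latent).
#' @export
build_style_generator <- function(config = generator_config(use_style = TRUE), seed = 0L) {
  config$use_style <- TRUE
  build_generator(config, seed = seed)
}

#' Map a latent to a style vector
#'
#' Runs the shared mapping network (four fully connected layers with
#' leaky-ReLU) of a style generator on standard-normal latents.
#'
#' @param z Numeric vector of length `latent_dim`, or a
#'   `latent_dim x n` matrix of column latents.
#' @param model A style generator from [build_style_generator()].
#' @return Matrix of style vectors, one column per latent.
#' @export
map_latent <- function(z, model) {
  cfg <- model$config
  if (!cfg$use_style) stop("model has no mapping network")
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  if (nrow(z) != cfg$latent_dim) stop("latent length mismatch")
  stop_if_not_finite(z, "latent")
  ag_value(mapping_forward(model, z, grad = FALSE))
}

mapping_forward <- function(model, z, grad) {
  h <- z
  for (j in 1:4) {
    h <- ag_lrelu(ag_linear(h, pget(model, paste0("map_fc", j, "_W"), grad),
                            pget(model, paste0("map_fc", j, "_b"), grad)), 0.2)
  }
  h
}

style_head_forward <- function(model, i, w, grad) {
  h <- w
  for (j in 1:3) {
    h <- ag_lrelu(ag_linear(h, pget(model, paste0("sty", i, "_fc", j, "_W"), grad),
                            pget(model, paste0("sty", i, "_fc", j, "_b"), grad)), 0.2)
  }
  ag_linear(h, pget(model, paste0("sty", i, "_fc4_W"), grad),
            pget(model, paste0("sty", i, "_fc4_b"), grad))
}

#' Run a generator forward
#'
#' @param model Generator model object.
#' @param sketch Condition image(s) in `[0,1]`: array `(H, W)`, `(H, W, 1)`
#'   or batch `(H, W, 1, N)`.
#' @param latent Optional `latent_dim x N` latent matrix (style models).
#' @param grad Build the autodiff graph (training) or return a plain array.
#' @return Generated image(s) in `[-1, 1]`, dim `(H, W, 1, N)` (a node when
#'   `grad = TRUE`).
#' @export
generator_forward <- function(model, sketch, latent = NULL, grad = FALSE) {
  cfg <- model$config
  x <- as_batch(ag_value(sketch))
  d <- dim(x); N <- d[4]
  if (d[1] != cfg$image_size || d[2] != cfg$image_size || d[3] != 1L)
    stop("sketch must be ", cfg$image_size, "x", cfg$image_size, "x1")
  if (cfg$use_style) {
    if (is.null(latent)) stop("style generator requires a latent")
    lv <- ag_value(latent)
    if (is.null(dim(lv))) lv <- matrix(lv, ncol = N)
    if (nrow(lv) != cfg$latent_dim || ncol(lv) != N) stop("latent length mismatch")
    w <- mapping_forward(model, lv, grad)
  }
  h <- 2 * x - 1
  skips <- vector("list", cfg$depth)
  size <- cfg$image_size
  for (i in seq_len(cfg$depth)) {
    h <- ag_conv2d(h, pget(model, paste0("enc", i, "_W"), grad),
                   pget(model, paste0("enc", i, "_b"), grad), stride = 2L, pad = 1L)
    size <- size %/% 2L
    if (i > 1L && size > 1L) h <- ag_instnorm(h)
    h <- ag_lrelu(h, 0.2)
    skips[[i]] <- h
  }
  for (i in seq_len(cfg$depth)) {
    last <- i == cfg$depth
    if (cfg$use_style) {
      s <- style_head_forward(model, i, w, grad)
      h <- ag_upsample2(h)
      h <- ag_modconv2d(h, pget(model, paste0("dec", i, "_W"), grad), s,
                        pget(model, paste0("dec", i, "_b"), grad),
                        demodulate = cfg$demodulate)
    } else {
      h <- ag_tconv2d(h, pget(model, paste0("dec", i, "_W"), grad),
                      pget(model, paste0("dec", i, "_b"), grad))
    }
    if (last) {
      h <- ag_tanh(h)
    } else {
      if (!cfg$use_style) h <- ag_instnorm(h)
      h <- ag_relu(h)
      h <- ag_concat_c(h, skips[[cfg$depth - i]])
    }
  }
  h
}

#' Build the PatchGAN discriminator
#'
#' Conditional discriminator: the sketch and the (real or generated) CT
#' image are concatenated channelwise and passed through four 4x4 stride-2
#' convolutions (64/128/256/512 at `base_channels = 64`; leaky-ReLU 0.2,
#' instance norm except at the first stage) and a 1-channel 4x4 head whose
#' sigmoid outputs form a patch grid of realness probabilities.
#'
#' @inheritParams build_generator
#' @return A model object.
#' @export
build_discriminator <- function(config = generator_config(), seed = 0L) {
  model <- new.env(parent = emptyenv())
  model$params <- list()
  model$config <- config
  model$type <- "patch_d"
  ch <- pmin(config$base_channels * c(1L, 2L, 4L, 8L), config$base_channels * 8L)
  nlay <- min(4L, config$depth - 1L)
  model$nlay <- nlay
  local_seed(seed, {
    cin <- 2L
    for (i in seq_len(nlay)) {
      model$params[[paste0("d", i, "_W")]] <- ag_leaf(winit(4L, 4L, cin, ch[i]))
      model$params[[paste0("d", i, "_b")]] <- ag_leaf(numeric(ch[i]))
      cin <- ch[i]
    }
    model$params[["head_W"]] <- ag_leaf(winit(4L, 4L, cin, 1L))
    model$params[["head_b"]] <- ag_leaf(numeric(1L))
  })
  class(model) <- c("sk_discriminator", "sk_model")
  model
}

#' Run the discriminator on (sketch, image) pairs
#'
#' @param model Discriminator from [build_discriminator()].
#' @param sketch Condition image(s) in `[0,1]`, `(H, W, 1, N)`.
#' @param image CT image(s) in `[-1, 1]`, `(H, W, 1, N)`.
#' @param grad Build the autodiff graph.
#' @return Patch probabilities in `(0,1)`, dim `(h, w, 1, N)`.
#' @export
discriminator_forward <- function(model, sketch, image, grad = FALSE) {
  s <- as_batch(ag_value(sketch))
  imb <- as_batch(ag_value(image))
  if (!all(dim(s)[1:2] == dim(imb)[1:2])) stop("sketch/image shape mismatch")
  x <- ag_concat_c(2 * s - 1, if (is_ag_node(image)) image else imb)
  for (i in seq_len(model$nlay)) {
    x <- ag_conv2d(x, pget(model, paste0("d", i, "_W"), grad),
                   pget(model, paste0("d", i, "_b"), grad), stride = 2L, pad = 1L)
    if (i > 1L) x <- ag_instnorm(x)
    x <- ag_lrelu(x, 0.2)
  }
  x <- ag_conv2d(x, pget(model, "head_W", grad), pget(model, "head_b", grad),
                 stride = 1L, pad = 1L)
  ag_sigmoid(x)
}

#' Style-modulated convolution (standalone operation)
#'
#' Rescales each input-channel slice of a 3x3 (or any odd) kernel by a style
#' scale, optionally demodulates each output channel to unit norm
#' (`1/sqrt(sum(k'^2) + 1e-8)`), and convolves at stride 1 with half-kernel
#' padding. With unit scales and demodulation off this is a plain
#' convolution.
#'
#' @param features Input array `(H, W, Cin)` or `(H, W, Cin, N)`.
#' @param kernel Kernel array `(kh, kw, Cin, Cout)`.
#' @param style_scales Numeric vector of length `Cin` (or `Cin x N` matrix).
#' @param demodulate Apply weight demodulation (default TRUE).
#' @return Array `(H, W, Cout, N)`.
#' @export
modulated_conv <- function(features, kernel, style_scales, demodulate = TRUE) {
  x <- as_batch(features)
  dk <- dim(kernel)
  if (length(dk) != 4L) stop("kernel must be (kh, kw, Cin, Cout)")
  sv <- style_scales
  if (is.null(dim(sv))) sv <- matrix(sv, ncol = dim(x)[4])
  if (nrow(sv) != dk[3]) stop("style_scales length must equal input channel count")
  ag_modconv2d(x, kernel, sv, b = NULL, demodulate = demodulate)
}

#' Draw standard-normal latents
#'
#' @param n Number of latents.
#' @param latent_dim Latent length.
#' @param seed Optional integer seed.
#' @return `latent_dim x n` matrix.
#' @export
sample_latent <- function(n, latent_dim = 512L, seed = NULL) {
  draw <- function() matrix(stats::rnorm(latent_dim * n), latent_dim, n)
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Generate images from a sketch
#'
#' Baseline generators are one-to-one: all `n` outputs are identical and the
#' latent is ignored. Style generators draw `n` fresh standard-normal
#' latents (or use `latent` if supplied for `n = 1`), yielding one-to-many
#' generation.
#'
#' @param model Generator model.
#' @param sketch Condition image in `[0,1]` (`H x W` matrix).
#' @param n Number of images to generate.
#' @param latent Optional fixed latent (style model, `n = 1`).
#' @param seed Integer seed for latent draws.
#' @return List of `n` images in `[-1, 1]` (`H x W` matrices).
#' @export
generate_images <- function(model, sketch, n = 1L, latent = NULL, seed = 0L) {
  if (n < 1L) stop("n must be >= 1")
  cfg <- model$config
  sk <- as_batch(sketch)
  if (!cfg$use_style) {
    out <- generator_forward(model, sk, grad = FALSE)
    img <- matrix(out[, , 1L, 1L], dim(out)[1], dim(out)[2])
    return(rep(list(img), n))
  }
  if (!is.null(latent)) {
    if (n != 1L) stop("fixed latent implies n = 1")
    lats <- matrix(latent, ncol = 1L)
  } else {
    lats <- sample_latent(n, cfg$latent_dim, seed = seed)
  }
  skb <- array(rep(sk, n), c(dim(sk)[1:3], n))
  out <- generator_forward(model, skb, latent = lats, grad = FALSE)
  lapply(seq_len(n), function(i) matrix(out[, , 1L, i], dim(out)[1], dim(out)[2]))
}

#' Count model parameters
#' @param model A model object.
#' @return Total number of scalar parameters.
#' @export
model_parameter_count <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

model_params <- function(model) model$params

#' Save / load a model bundle
#'
#' Checkpoints a generator/discriminator pair (or single model) with its
#' configuration into one archive.
#'
#' @param bundle Named list of model objects plus optional metadata.
#' @param path File path.
#' @return `load_bundle` returns the reconstructed bundle.
#' @export
save_bundle <- function(bundle, path) {
  ser <- lapply(bundle, function(m) {
    if (inherits(m, "sk_model"))
      list(kind = "model", type = m$type, nlay = m$nlay, config = unclass(m$config),
           weights = lapply(m$params, ag_value))
    else list(kind = "meta", value = m)
  })
  saveRDS(ser, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  ser <- readRDS(path)
  lapply(ser, function(s) {
    if (identical(s$kind, "meta")) return(s$value)
    cfg <- structure(s$config, class = "sk_gen_config")
    m <- if (identical(s$type, "patch_d")) build_discriminator(cfg)
         else build_generator(cfg)
    for (nm in names(s$weights)) m$params[[nm]]$value <- s$weights[[nm]]
    m
  })
}
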