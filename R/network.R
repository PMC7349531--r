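#' Declarative architecture specification
#'
#' Describes the dense encoder--decoder segmentation network: four encoder
#' dense blocks (two 3x3 convolutions each, in-block depth concatenation and
#' a 1x1 bottleneck, followed by 2x2 max pooling with recorded indices) and
#' four mirrored decoder blocks (index-driven max unpooling, two 3x3
#' convolutions, a three-way concatenation that imports the encoder block's
#' first-convolution feature, and a bottleneck), ending in a per-pixel
#' softmax classifier.
#'
#' @param input_rows,input_cols Default input size in pixels. The network is
#'   fully convolutional, so these are a convention for shape tables and
#'   parameter-free of the actual value; both must be at least 16 (four
#'   spatial halvings).
#' @param input_channels Number of input channels (3 for color fundus images).
#' @param block_widths Integer vector of length 4: filter count of each dense
#'   block (64, 128, 256, 512 for the full-size network).
#' @param n_classes Number of output classes (2: background / pigment).
#' @param kernel_size Spatial size of the main convolutions (3).
#' @return An object of class `rps_spec`.
#' @examples
#' spec <- rps_spec()
#' small <- rps_spec(block_widths = c(8, 16, 32, 64))
#' @export
rps_spec <- function(input_rows = 400L, input_cols = 300L,
                     input_channels = 3L,
                     block_widths = c(64L, 128L, 256L, 512L),
                     n_classes = 2L, kernel_size = 3L) {
  if (length(block_widths) != 4L)
    stop("block_widths must have length 4 (four dense blocks)", call. = FALSE)
  if (any(block_widths <= 0))
    stop("block widths must be positive", call. = FALSE)
  if (input_rows <= 0 || input_cols <= 0 || input_channels <= 0)
    stop("input dimensions must be positive", call. = FALSE)
  if (n_classes < 2L)
    stop("n_classes must be at least 2", call. = FALSE)
  structure(list(input_rows = as.integer(input_rows),
                 input_cols = as.integer(input_cols),
                 input_channels = as.integer(input_channels),
                 block_widths = as.integer(block_widths),
                 n_classes = as.integer(n_classes),
                 kernel_size = as.integer(kernel_size)),
            class = "rps_spec")
}

#' @export
print.rps_spec <- function(x, ...) {
  cat("Network spec:", x$input_rows, "x", x$input_cols, "x",
      x$input_channels, "input;",
      "block widths", paste(x$block_widths, collapse = "/"),
      ";", x$n_classes, "classes\n")
  invisible(x)
}

#' Read or write a network spec as YAML
#'
#' @param spec An `rps_spec`.
#' @param path File path.
#' @return `read_spec_yaml` returns an `rps_spec`.
#' @export
write_spec_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "rps_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  rps_spec(input_rows = v$input_rows, input_cols = v$input_cols,
           input_channels = v$input_channels,
           block_widths = unlist(v$block_widths),
           n_classes = v$n_classes, kernel_size = v$kernel_size)
}

# Decoder block j's second convolution (and its bottleneck) narrow to the
# next-shallower block width, or to n_classes in the outermost block.
.dec_out_width <- function(spec, j) {
  if (j > 1L) spec$block_widths[j - 1L] else spec$n_classes
}

#' Layer table of the network
#'
#' One row per layer in execution order: the eight encoder and eight decoder
#' 3x3 convolutions, the eight 1x1 bottlenecks, batch-norm + ReLU stages,
#' concatenations, the four pooling / four unpooling layers, and the softmax
#' pixel classifier. Layers named after the field convention
#' (EC1-A, Ecat-1, Bneck-1, Pool-1, Unpool-4, DC4-B, Dcat-4, ...).
#'
#' @param spec An `rps_spec` (or an `rps_network`, whose spec is used).
#' @return A data.frame with columns `name`, `kind`, `input_channels`,
#'   `output_channels`, `has_bias`.
#' @export
network_layers <- function(spec) {
  if (inherits(spec, "rps_network")) spec <- spec$spec
  stopifnot(inherits(spec, "rps_spec"))
  w <- spec$block_widths
  rows <- list()
  add <- function(name, kind, cin, cout, bias = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, input_channels = cin,
      output_channels = cout, has_bias = bias)
  cin <- spec$input_channels
  for (i in 1:4) {
    add(sprintf("EC%d-A", i), "conv3x3", cin, w[i], TRUE)
    add(sprintf("EC%d-A-bn", i), "batchnorm_relu", w[i], w[i])
    add(sprintf("EC%d-B", i), "conv3x3", w[i], w[i], TRUE)
    add(sprintf("Ecat-%d", i), "concat", 2L * w[i], 2L * w[i])
    add(sprintf("Bneck-%d", i), "conv1x1_bottleneck", 2L * w[i], w[i], TRUE)
    add(sprintf("Bneck-%d-bn", i), "batchnorm_relu", w[i], w[i])
    add(sprintf("Pool-%d", i), "maxpool", w[i], w[i])
    cin <- w[i]
  }
  for (j in 4:1) {
    wa <- .dec_out_width(spec, j)
    add(sprintf("Unpool-%d", j), "unpool", w[j], w[j])
    add(sprintf("DC%d-B", j), "conv3x3", w[j], w[j], TRUE)
    add(sprintf("DC%d-B-bn", j), "batchnorm_relu", w[j], w[j])
    add(sprintf("DC%d-A", j), "conv3x3", w[j], wa, TRUE)
    cat_ch <- 2L * w[j] + wa  # DC-B out + DC-A out + imported EC-A out
    add(sprintf("Dcat-%d", j), "concat", cat_ch, cat_ch)
    add(sprintf("Bneck-%d", 9L - j), "conv1x1_bottleneck", cat_ch, wa, TRUE)
    add(sprintf("Bneck-%d-bn", 9L - j), "batchnorm_relu", wa, wa)
  }
  add("Softmax", "softmax_pixel_classifier", spec$n_classes, spec$n_classes)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.he_init <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  array(stats::rnorm(kh * kw * cin * cout, sd = sd), dim = c(kh, kw, cin, cout))
}

#' Construct the network
#'
#' Allocates and initializes all trainable parameters (He-normal convolution
#' weights, zero biases, batch-norm scale 1 / shift 0) for the architecture
#' described by `spec`.
#'
#' @param spec An `rps_spec`.
#' @param seed Integer seed for weight initialization (reproducible builds).
#' @return An object of class `rps_network`: the spec, the layer table, and
#'   a named parameter list.
#' @examples
#' net <- build_network(rps_spec(block_widths = c(4, 8, 16, 32)), seed = 1)
#' count_trainable_parameters(net)
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "rps_spec"))
  layers <- network_layers(spec)
  k <- spec$kernel_size
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  params <- list()
  for (r in seq_len(nrow(layers))) {
    ly <- layers[r, ]
    if (ly$kind %in% c("conv3x3", "conv1x1_bottleneck")) {
      kk <- if (ly$kind == "conv3x3") k else 1L
      params[[ly$name]] <- list(
        w = .he_init(kk, kk, ly$input_channels, ly$output_channels),
        b = numeric(ly$output_channels))
    } else if (ly$kind == "batchnorm_relu") {
      params[[ly$name]] <- list(gamma = rep(1, ly$output_channels),
                                beta = numeric(ly$output_channels))
    }
  }
  structure(list(spec = spec, layers = layers, params = params, seed = seed),
            class = "rps_network")
}

.Random.seed_get <- function()
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.rps_network <- function(x, ...) {
  cat("Encoder-decoder segmentation network\n")
  print(x$spec)
  cat(sprintf("%d layers, %s trainable parameters\n", nrow(x$layers),
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Kernel weights + biases for every convolution, plus scale and shift for
#' every batch-norm stage. Concatenation, pooling, unpooling and softmax
#' layers hold no parameters.
#'
#' @param net An `rps_network` (or an `rps_spec`, counted without building).
#' @return Integer-valued total.
#' @export
count_trainable_parameters <- function(net) {
  if (inherits(net, "rps_network")) {
    if (length(net$params) == 0) return(0)
    return(sum(vapply(net$params,
                      function(p) sum(vapply(p, length, 0L)), 0)))
  }
  layers <- network_layers(net)
  k <- net$kernel_size
  total <- 0
  for (r in seq_len(nrow(layers))) {
    ly <- layers[r, ]
    total <- total + switch(
      ly$kind,
      conv3x3 = k * k * ly$input_channels * ly$output_channels +
        ly$output_channels,
      conv1x1_bottleneck = ly$input_channels * ly$output_channels +
        ly$output_channels,
      batchnorm_relu = 2 * ly$output_channels,
      0)
  }
  total
}

#' Shape propagation table
#'
#' Pure spatial/channel bookkeeping, no numerics: 3x3 and 1x1 convolutions
#' preserve spatial size (symmetric padding), pooling floor-halves each
#' dimension, unpooling restores the recorded pre-pool size of its paired
#' pooling layer.
#'
#' @param net An `rps_network` or `rps_spec`.
#' @param input_dims Optional `c(rows, cols)`; defaults to the spec's.
#' @param include_bn Keep the batch-norm rows (shape-neutral)? Default FALSE.
#' @return data.frame with columns `name`, `rows`, `cols`, `channels`.
#' @examples
#' layer_shape_table(rps_spec())  # reproduces the full-size layout
#' @export
layer_shape_table <- function(net, input_dims = NULL, include_bn = FALSE) {
  spec <- if (inherits(net, "rps_network")) net$spec else net
  stopifnot(inherits(spec, "rps_spec"))
  if (is.null(input_dims))
    input_dims <- c(spec$input_rows, spec$input_cols)
  if (any(input_dims < 16))
    stop("input dims must be at least 16 x 16 (four spatial halvings)",
         call. = FALSE)
  layers <- network_layers(spec)
  r <- input_dims[1]; cl <- input_dims[2]
  prepool <- list()
  out <- vector("list", nrow(layers))
  for (i in seq_len(nrow(layers))) {
    ly <- layers[i, ]
    if (ly$kind == "maxpool") {
      stage <- as.integer(sub("Pool-", "", ly$name))
      prepool[[stage]] <- c(r, cl)
      r <- r %/% 2L; cl <- cl %/% 2L
    } else if (ly$kind == "unpool") {
      stage <- as.integer(sub("Unpool-", "", ly$name))
      r <- prepool[[stage]][1]; cl <- prepool[[stage]][2]
    }
    out[[i]] <- data.frame(name = ly$name, rows = r, cols = cl,
                           channels = ly$output_channels)
  }
  tab <- do.call(rbind, out)
  if (!include_bn) tab <- tab[!grepl("-bn$", tab$name), ]
  rownames(tab) <- NULL
  tab
}
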