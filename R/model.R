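## Model configuration and assembly of the two-stream bidirectional network.

#' Architecture configuration
#'
#' Collects every architecture hyperparameter of the two-stream network. The
#' defaults give the full-size model; tests and CPU-scale experiments shrink
#' `widths`, `decoder_width` and `input_size`.
#'
#' @param input_size square input resolution in pixels after preprocessing.
#' @param widths integer vector of 6 per-stage channel counts of the backbone.
#' @param expansion expansion factor of the inverted-residual backbone blocks.
#' @param cfs_stages stages (subset of 1..6) that apply cross-modality feature
#'   supplementation; the default is the first four stages.
#' @param bam_reduction,bam_dilation bottleneck attention hyperparameters.
#' @param share_high_stages share the stage 5-6 backbone weights between the
#'   color and depth branches?
#' @param depth_input_mode `"replicate3"` replicates the depth channel to the
#'   3-channel backbone interface; `"learned1to3"` uses a learned 1x1 conv.
#' @param decoder_width working channel width of the decoder (even).
#' @param rfb_dilations dilation rates of the receptive-field blocks.
#' @param head_hidden hidden width of the regression head MLP.
#' @param fusion_scheme decoder cross-modality step: `"cff"` (default) or the
#'   ablation variants `"addition"`, `"max"`, `"concatenation"`.
#' @param modality `"rgbd"` (two-stream), or single-branch `"rgb"` / `"depth"`.
#' @param topology `"multiscale"` (the full architecture), `"early"`
#'   (4-channel input, one backbone) or `"late"` (independent backbones,
#'   concatenated final features).
#' @param loss training loss: `"l1"` (default), `"l2"` or `"smooth_l1"`.
#' @param target_norm z-score the weight targets with training-split
#'   statistics (inverted at prediction)?
#' @return list of class `model_config`.
#' @export
model_config <- function(input_size = 224L,
                         widths = c(16L, 24L, 32L, 48L, 64L, 96L),
                         expansion = 3,
                         cfs_stages = 1:4,
                         bam_reduction = 16L,
                         bam_dilation = 4L,
                         share_high_stages = TRUE,
                         depth_input_mode = c("replicate3", "learned1to3"),
                         decoder_width = 64L,
                         rfb_dilations = c(1L, 3L, 5L),
                         head_hidden = 128L,
                         fusion_scheme = c("cff", "addition", "max", "concatenation"),
                         modality = c("rgbd", "rgb", "depth"),
                         topology = c("multiscale", "early", "late"),
                         loss = c("l1", "l2", "smooth_l1"),
                         target_norm = FALSE) {
  stopifnot(length(widths) == 6L, all(widths >= 1L), input_size >= 16L)
  if (decoder_width %% 2L != 0L) stop("decoder_width must be even")
  cfg <- list(input_size = as.integer(input_size),
              widths = as.integer(widths),
              expansion = expansion,
              cfs_stages = sort(unique(as.integer(cfs_stages))),
              bam_reduction = as.integer(bam_reduction),
              bam_dilation = as.integer(bam_dilation),
              share_high_stages = isTRUE(share_high_stages),
              depth_input_mode = match.arg(depth_input_mode),
              decoder_width = as.integer(decoder_width),
              rfb_dilations = as.integer(rfb_dilations),
              head_hidden = as.integer(head_hidden),
              fusion_scheme = match.arg(fusion_scheme),
              modality = match.arg(modality),
              topology = match.arg(topology),
              loss = match.arg(loss),
              target_norm = isTRUE(target_norm))
  if (length(cfg$cfs_stages) && (min(cfg$cfs_stages) < 1L || max(cfg$cfs_stages) > 6L))
    stop("cfs_stages must lie in 1..6")
  class(cfg) <- "model_config"
  cfg
}

#' Write a model configuration as a JSON key-value file
#' @param config a [model_config()].
#' @param path output path.
#' @export
write_model_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model configuration from a JSON key-value file
#'
#' Unknown keys are rejected; missing keys take the documented defaults.
#' @param path JSON path as written by [write_model_config()].
#' @return a validated [model_config()].
#' @export
read_model_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown model_config keys: ", paste(extra, collapse = ", "))
  do.call(model_config, vals)
}

## one backbone branch: stem (stage 1) + five strided stages
nn_backbone <- function(cfg, cin = 3L, name = "bb") {
  w <- cfg$widths
  list(stem = nn_conv(cin, w[1], k = 3L, stride = 2L, name = paste0(name, ".stem")),
       s2 = nn_invres(w[1], w[2], stride = 2L, expansion = cfg$expansion,
                      name = paste0(name, ".s2")),
       s3 = nn_invres(w[2], w[3], stride = 2L, expansion = cfg$expansion,
                      name = paste0(name, ".s3")),
       s4 = nn_invres(w[3], w[4], stride = 2L, expansion = cfg$expansion,
                      name = paste0(name, ".s4")),
       s5 = nn_invres(w[4], w[5], stride = 2L, expansion = cfg$expansion,
                      name = paste0(name, ".s5")),
       s6 = nn_invres(w[5], w[6], stride = 2L, expansion = cfg$expansion,
                      name = paste0(name, ".s6")))
}

## each stage ends in a per-sample RMS normalization: the backbone's stand-in
## for batch normalization, and what keeps the downstream multiplicative
## fusion (element-wise products in FF) numerically bounded
backbone_stage_apply <- function(bb, i, x) {
  f <- if (i == 1L) ag_relu(conv_apply(bb$stem, x))
       else invres_apply(bb[[paste0("s", i)]], x)
  ag_rmsnorm(f)
}

#' Build the weight-estimation network
#'
#' Assembles encoder (two branches, CFS at the configured stages, optionally
#' shared stages 5-6), decoder (three CFF levels) and regression head, with
#' randomly initialized parameters.
#'
#' @param config a [model_config()].
#' @param init_seed integer seed for parameter initialization.
#' @return list of class `weight_model`.
#' @export
build_model <- function(config, init_seed = 1L) {
  local_seed(init_seed, {
    m <- list(config = config)
    w <- config$widths
    if (config$topology == "early") {
      m$backbone <- nn_backbone(config, cin = 4L, name = "early")
      m$head <- nn_head(w[6], config$head_hidden)
    } else if (config$modality %in% c("rgb", "depth")) {
      m$backbone <- nn_backbone(config, cin = 3L, name = config$modality)
      m$head <- nn_head(w[6], config$head_hidden)
    } else if (config$topology == "late") {
      m$bbR <- nn_backbone(config, cin = 3L, name = "R")
      m$bbD <- nn_backbone(config, cin = 3L, name = "D")
      m$head <- nn_head(2L * w[6], config$head_hidden)
    } else {
      m$bbR <- nn_backbone(config, cin = 3L, name = "R")
      m$bbD <- nn_backbone(config, cin = 3L, name = "D")
      if (config$share_high_stages) {
        m$bbD$s5 <- m$bbR$s5
        m$bbD$s6 <- m$bbR$s6
      }
      m$cfs <- list()
      for (i in config$cfs_stages)
        m$cfs[[as.character(i)]] <-
          nn_cfs(w[i], config$bam_reduction, config$bam_dilation,
                 name = paste0("cfs", i))
      dw <- config$decoder_width
      m$decoder <- list(
        high = nn_cff(w[5], w[6], dw, has_prev = FALSE,
                      fusion_scheme = config$fusion_scheme,
                      rfb_dilations = config$rfb_dilations, name = "cff.high"),
        middle = nn_cff(w[3], w[4], dw, has_prev = TRUE, c_prev = dw,
                        fusion_scheme = config$fusion_scheme,
                        rfb_dilations = config$rfb_dilations, name = "cff.mid"),
        low = nn_cff(w[1], w[2], dw, has_prev = TRUE, c_prev = 2L * dw,
                     fusion_scheme = config$fusion_scheme,
                     rfb_dilations = config$rfb_dilations, name = "cff.low"))
      m$head <- nn_head(2L * dw, config$head_hidden)
    }
    if (config$depth_input_mode == "learned1to3" && config$topology != "early")
      m$d3 <- nn_conv(1L, 3L, k = 1L, name = "d3")
    class(m) <- "weight_model"
    m
  })
}

#' Regression head constructor: GAP then a two-layer perceptron.
#' @keywords internal
nn_head <- function(cin, hidden, name = "head") {
  list(kind = "head", cin = cin,
       fc1 = nn_linear(cin, hidden, name = paste0(name, ".fc1")),
       fc2 = nn_linear(hidden, 1L, name = paste0(name, ".fc2")))
}

#' Map a decoder feature map to scalar weights
#'
#' Global average pooling followed by a two-layer perceptron with one
#' nonlinearity; no output activation (weights are unbounded above).
#' @param head a regression head from `nn_head()`.
#' @param f `ag_tensor` feature map `(H, W, C, N)`.
#' @return `ag_tensor` of shape `(1, N)`.
#' @export
regress <- function(head, f) {
  if (any(!is.finite(f$v)))
    stop("regress: non-finite feature values")
  d <- dim(f$v)
  x <- ag_reshape(ag_gap(f), c(d[3], d[4]))
  linear_apply(head$fc2, ag_relu(linear_apply(head$fc1, x)))
}

#' Run the two-branch encoder
#'
#' Stages in `cfs_stages` apply the backbone stage followed by CFS, feeding
#' the supplemented features to the next stage. With
#' `config$share_high_stages` stages 5-6 of the two branches are the same
#' module objects.
#'
#' @param model a `weight_model` with two-stream topology.
#' @param rgb,depth3 input `ag_tensor`s of shape `(S, S, 3, N)`.
#' @param acts optional environment collecting named activations.
#' @return list with `pyramidR` and `pyramidD`, each a list of 6 tensors with
#'   non-increasing spatial sizes.
#' @export
encode <- function(model, rgb, depth3, acts = NULL) {
  cfg <- model$config
  pyrR <- vector("list", 6L)
  pyrD <- vector("list", 6L)
  xR <- rgb
  xD <- depth3
  for (i in 1:6) {
    fR <- backbone_stage_apply(model$bbR, i, xR)
    fD <- backbone_stage_apply(model$bbD, i, xD)
    if (i %in% cfg$cfs_stages) {
      s <- cfs_apply(model$cfs[[as.character(i)]], fR, fD)
      fR <- s$bfR
      fD <- s$bfD
    }
    pyrR[[i]] <- fR
    pyrD[[i]] <- fD
    if (!is.null(acts)) {
      acts[[paste0("encoder.R.stage", i)]] <- fR
      acts[[paste0("encoder.D.stage", i)]] <- fD
    }
    xR <- fR
    xD <- fD
  }
  list(pyramidR = pyrR, pyramidD = pyrD)
}

#' Run the decoder over the two feature pyramids
#'
#' CFF-high fuses stages 5-6 (no previous input), CFF-middle stages 3-4 plus
#' the high output, CFF-low stages 1-2 plus the middle output; information
#' flows strictly coarse to fine.
#' @param model a `weight_model`.
#' @param pyramidR,pyramidD lists of 6 per-stage tensors from [encode()].
#' @inheritParams encode
#' @return fused `ag_tensor` feature map at the stage-1/2 spatial scale.
#' @export
decode <- function(model, pyramidR, pyramidD, acts = NULL) {
  if (length(pyramidR) != 6L || length(pyramidD) != 6L)
    stop("decode: expected six features per branch")
  dec <- model$decoder
  ## each level is RMS-normalized (same per-sample scale control as the
  ## encoder stages) before feeding the next level / the regression head
  f_high <- ag_rmsnorm(cff_apply(dec$high, pyramidR[[5]], pyramidR[[6]],
                                 pyramidD[[5]], pyramidD[[6]]))
  f_mid <- ag_rmsnorm(cff_apply(dec$middle, pyramidR[[3]], pyramidR[[4]],
                                pyramidD[[3]], pyramidD[[4]], f_prev = f_high))
  f_low <- ag_rmsnorm(cff_apply(dec$low, pyramidR[[1]], pyramidR[[2]],
                                pyramidD[[1]], pyramidD[[2]], f_prev = f_mid))
  if (!is.null(acts)) {
    acts[["decoder.high"]] <- f_high
    acts[["decoder.middle"]] <- f_mid
    acts[["decoder.low"]] <- f_low
  }
  f_low
}

## depth (S,S,1,N) tensor -> 3-channel tensor per config
depth_to3 <- function(model, depth) {
  if (!is.null(model$d3)) return(conv_apply(model$d3, depth))
  v <- depth$v
  d <- dim(v)
  v3 <- array(v, c(d[1], d[2], 1L, d[4]))[, , c(1L, 1L, 1L), , drop = FALSE]
  t3 <- ag_node(v3, list(depth), function(g) {
    ag_acc(depth, array(g[, , 1L, ] + g[, , 2L, ] + g[, , 3L, ],
                        dim(depth$v)))
  })
  t3
}

#' Full forward pass of the network
#'
#' @param model a `weight_model`.
#' @param rgb numeric array `(S, S, 3, N)` (normalized).
#' @param depth numeric array `(S, S, 1, N)` (normalized).
#' @param acts optional environment to collect named activations (for
#'   gradient-weighted activation maps).
#' @return `ag_tensor` of predictions, shape `(1, N)` (on the normalized
#'   target scale if the model was trained with `target_norm`).
#' @export
model_forward <- function(model, rgb, depth, acts = NULL) {
  cfg <- model$config
  tr <- ag_tensor(rgb)
  td <- ag_tensor(depth)
  if (cfg$topology == "early") {
    x <- ag_tensor(abind4(rgb, depth))
    f <- x
    for (i in 1:6) f <- backbone_stage_apply(model$backbone, i, f)
    if (!is.null(acts)) acts[["encoder.stage6"]] <- f
    return(regress(model$head, f))
  }
  if (cfg$modality == "rgb") {
    f <- tr
    for (i in 1:6) f <- backbone_stage_apply(model$backbone, i, f)
    if (!is.null(acts)) acts[["encoder.stage6"]] <- f
    return(regress(model$head, f))
  }
  if (cfg$modality == "depth") {
    f <- depth_to3(model, td)
    for (i in 1:6) f <- backbone_stage_apply(model$backbone, i, f)
    if (!is.null(acts)) acts[["encoder.stage6"]] <- f
    return(regress(model$head, f))
  }
  d3 <- depth_to3(model, td)
  if (cfg$topology == "late") {
    fR <- tr
    fD <- d3
    for (i in 1:6) {
      fR <- backbone_stage_apply(model$bbR, i, fR)
      fD <- backbone_stage_apply(model$bbD, i, fD)
    }
    if (!is.null(acts)) {
      acts[["encoder.R.stage6"]] <- fR
      acts[["encoder.D.stage6"]] <- fD
    }
    return(regress(model$head, ag_concat_c(list(fR, fD))))
  }
  pyr <- encode(model, tr, d3, acts = acts)
  fused <- decode(model, pyr$pyramidR, pyr$pyramidD, acts = acts)
  regress(model$head, fused)
}

## concatenate rgb (S,S,3,N) and depth (S,S,1,N) into a 4-channel array
abind4 <- function(rgb, depth) {
  d <- dim(rgb)
  out <- array(0, c(d[1], d[2], 4L, d[4]))
  out[, , 1:3, ] <- rgb
  out[, , 4L, ] <- depth
  out
}
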