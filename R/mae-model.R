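## Masked-autoencoder model: parameter initialization and the full
## forward/backward pass. Tiles are tokenized into tokenSize^2-pixel
## tokens; the encoder sees only the visible tokens of each tile, the
## decoder reconstructs all tokens from the encoder latents plus a learned
## mask token, and the loss is the MSE over the masked tokens' pixels.

maeArch <- function(cfg) {
  list(
    tileSize = cfg$tileSize, tokenSize = cfg$tokenSize,
    embedDim = cfg$embedDim, encoderDepth = cfg$encoderDepth,
    encoderHeads = cfg$encoderHeads, decoderDim = cfg$decoderDim,
    decoderDepth = cfg$decoderDepth, mlpRatio = cfg$mlpRatio,
    tokensPerSide = cfg$tileSize %/% cfg$tokenSize,
    tokenCount = (cfg$tileSize %/% cfg$tokenSize)^2,
    tokenPixels = cfg$tokenSize^2
  )
}

initBlockParams <- function(D, H, mlpRatio, rmat) {
  Dh <- as.integer(round(D * mlpRatio))
  list(
    ln1g = rep(1, D), ln1b = rep(0, D),
    Wq = rmat(D, D), bq = rep(0, D),
    Wk = rmat(D, D), bk = rep(0, D),
    Wv = rmat(D, D), bv = rep(0, D),
    Wo = rmat(D, D), bo = rep(0, D),
    ln2g = rep(1, D), ln2b = rep(0, D),
    W1 = rmat(D, Dh), b1 = rep(0, Dh),
    W2 = rmat(Dh, D), b2 = rep(0, D)
  )
}

#' Initialize a masked autoencoder
#'
#' Builds an untrained [MAEModel-class] with the architecture implied by a
#' `RunConfig`: a linear patch embedding into `embedDim`-wide tokens, fixed
#' 2-D sine-cosine positional encodings, a pre-LayerNorm transformer
#' encoder, and a narrower transformer decoder that reconstructs pixel
#' tokens. Weights are drawn N(0, 0.02^2) from the given seed.
#'
#' @param cfg a `RunConfig`.
#' @param seed integer seed for the parameter draw (default
#'   `cfg$trainSeed`).
#' @return An [MAEModel-class].
#' @export
initMAE <- function(cfg, seed = cfg$trainSeed) {
  arch <- maeArch(cfg)
  set.seed(seed)
  rmat <- function(a, b) matrix(stats::rnorm(a * b, sd = 0.02), a, b)
  D <- arch$embedDim; Dd <- arch$decoderDim; P2 <- arch$tokenPixels
  params <- list(
    patchW = rmat(P2, D), patchB = rep(0, D),
    enc = lapply(seq_len(arch$encoderDepth), function(i)
      initBlockParams(D, arch$encoderHeads, arch$mlpRatio, rmat)),
    encLNg = rep(1, D), encLNb = rep(0, D),
    decW = rmat(D, Dd), decB = rep(0, Dd),
    maskTok = stats::rnorm(Dd, sd = 0.02),
    dec = lapply(seq_len(arch$decoderDepth), function(i)
      initBlockParams(Dd, arch$encoderHeads, arch$mlpRatio, rmat)),
    decLNg = rep(1, Dd), decLNb = rep(0, Dd),
    headW = rmat(Dd, P2), headB = rep(0, P2)
  )
  new("MAEModel", params = params, arch = arch,
      trainingLog = data.frame(epoch = integer(0), trainLoss = numeric(0),
                               valLoss = numeric(0)),
      seeds = c(train = as.integer(seed)))
}

## Tokenize a tile (tileSize x tileSize matrix) into a tokenCount x
## tokenPixels matrix; tokens row-major over the token grid, pixels
## row-major within each token.
tokenizeTile <- function(tile, tokenSize) {
  tps <- nrow(tile) %/% tokenSize
  out <- matrix(0, tps * tps, tokenSize * tokenSize)
  t_ <- 0L
  for (i in seq_len(tps)) {
    ri <- ((i - 1L) * tokenSize + 1L):(i * tokenSize)
    for (j in seq_len(tps)) {
      ci <- ((j - 1L) * tokenSize + 1L):(j * tokenSize)
      t_ <- t_ + 1L
      out[t_, ] <- as.numeric(t(tile[ri, ci]))
    }
  }
  out
}

## Forward + backward for one batch. tokens: (B*T) x P2 matrix grouped by
## tile. masks: B x T logical, TRUE = masked. Returns loss and gradients
## (same structure as params); with computeGrads = FALSE, forward only.
maeStep <- function(params, arch, tokens, masks, computeGrads = TRUE) {
  T_ <- arch$tokenCount
  B <- nrow(masks)
  H <- arch$encoderHeads
  stopifnot(nrow(tokens) == B * T_)
  posD <- sincosPosEnc(arch$tokensPerSide, arch$decoderDim)

  visPerTile <- T_ - sum(masks[1, ])
  visTok <- which(!t(masks))        # global row indices of visible tokens
  mskTok <- which(t(masks))         # global row indices of masked tokens
  allPos <- rep(seq_len(T_), B)

  ## encoder on visible tokens only; the encoder is position-free (a set
  ## encoder): token positions are supplied to the decoder only, so the
  ## latent space encodes content rather than within-tile location, which
  ## the downstream clustering relies on
  embed <- linearFwd(tokens[visTok, , drop = FALSE], params$patchW,
                     params$patchB)
  enc <- stackFwd(embed$out, params$enc, params$encLNg, params$encLNb,
                  B, visPerTile, H)

  ## decoder input: projected latents at visible slots, mask token elsewhere
  proj <- linearFwd(enc$out, params$decW, params$decB)
  Xd <- matrix(params$maskTok, B * T_, arch$decoderDim, byrow = TRUE)
  Xd[visTok, ] <- proj$out
  Xd <- Xd + posD[allPos, , drop = FALSE]
  dec <- stackFwd(Xd, params$dec, params$decLNg, params$decLNb, B, T_, H)
  head <- linearFwd(dec$out, params$headW, params$headB)

  resid <- head$out[mskTok, , drop = FALSE] - tokens[mskTok, , drop = FALSE]
  nPix <- length(resid)
  loss <- sum(resid^2) / nPix
  if (!is.finite(loss)) stop("training error: non-finite loss")
  if (!computeGrads) return(list(loss = loss))

  dPred <- matrix(0, B * T_, arch$tokenPixels)
  dPred[mskTok, ] <- 2 * resid / nPix
  hb <- linearBwd(dPred, head, params$headW)
  db <- stackBwd(hb$dX, dec, params$dec, params$decLNg, B, T_, H)
  dXd <- db$dX
  dMaskTok <- colSums(dXd[mskTok, , drop = FALSE])
  pb <- linearBwd(dXd[visTok, , drop = FALSE], proj, params$decW)
  eb <- stackBwd(pb$dX, enc, params$enc, params$encLNg, B, visPerTile, H)
  emb <- linearBwd(eb$dX, embed, params$patchW)

  grads <- list(
    patchW = emb$dW, patchB = emb$db,
    enc = eb$blockGrads, encLNg = eb$lnG, encLNb = eb$lnB,
    decW = pb$dW, decB = pb$db,
    maskTok = dMaskTok,
    dec = db$blockGrads, decLNg = db$lnG, decLNb = db$lnB,
    headW = hb$dW, headB = hb$db
  )
  list(loss = loss, grads = grads)
}

## Encoder-only forward on all tokens of B tiles (no masking); returns the
## (B*T) x D latent matrix after the final encoder LayerNorm.
maeEncode <- function(params, arch, tokens, B) {
  embed <- linearFwd(tokens, params$patchW, params$patchB)
  stackFwd(embed$out, params$enc, params$encLNg, params$encLNb,
           B, arch$tokenCount, arch$encoderHeads)$out
}
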