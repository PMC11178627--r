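# Policy application: each spec is gated by an independent uniform draw
# against its chance, then its magnitudes are drawn and the deterministic
# transform applied. The draw plan is materialised first so the same draws
# can be replayed across the channels of a multi-channel image.

# Draw one concrete application plan for (policy, image dims) from the
# current RNG stream. Each entry: name, applied flag, and concrete
# parameters for the deterministic transform.
.drawPlan <- function(policy, h, w) {
    lapply(policy@specs, function(spec) {
        applied <- runif(1) < spec@chance
        params <- NULL
        if (applied) {
            m <- spec@magnitude
            params <- switch(spec@name,
                translation = {
                    my <- round(m * h); mx <- round(m * w)
                    list(dy = if (my > 0) sample(seq(-my, my), 1L) else 0L,
                         dx = if (mx > 0) sample(seq(-mx, mx), 1L) else 0L)
                },
                cropping = {
                    size <- as.integer(m)
                    if (size > min(h, w))
                        stop("crop size exceeds image dimensions")
                    list(top = sample.int(h - size + 1L, 1L),
                         left = sample.int(w - size + 1L, 1L), size = size)
                },
                rotation = list(degrees = runif(1, -m, m)),
                occlusion = {
                    area <- round(m * h * w)
                    r <- runif(1, 0.5, 2)
                    rh <- max(1L, min(h, as.integer(round(sqrt(area * r)))))
                    rw <- max(1L, min(w, as.integer(round(area / rh))))
                    list(top = sample.int(h - rh + 1L, 1L),
                         left = sample.int(w - rw + 1L, 1L),
                         height = rh, width = rw)
                },
                noise = list(field = matrix(rnorm(h * w, 0, m), h, w)),
                list())
        }
        list(name = spec@name, applied = applied, params = params)
    })
}

.applyPlan <- function(img, plan) {
    for (step in plan) {
        if (!step$applied) next
        p <- step$params
        img <- switch(step$name,
            translation = translateImage(img, p$dy, p$dx),
            cropping = cropResize(img, p$top, p$left, p$size),
            rotation = rotateImage(img, p$degrees),
            hflip = flipImage(img, "horizontal"),
            vflip = flipImage(img, "vertical"),
            occlusion = occludeRect(img, p$top, p$left, p$height, p$width),
            noise = GrayImage(clip01(img@pixels + p$field)),
            equalisation = histEqualize(img),
            sharpening = sharpen(img),
            inversion = invertImage(img),
            stop("unknown augmentation '", step$name, "' in policy"))
    }
    img
}

#' Apply a stochastic augmentation policy
#'
#' Visits the policy's specs in order; each is applied iff an independent
#' uniform draw falls below its chance, with magnitudes drawn as each
#' operator specifies. The whole application is a deterministic function of
#' `(img, seed)`: the same seed and input always give the same output. The
#' empty policy is the exact identity.
#'
#' @param img a [GrayImage-class].
#' @param policy an [AugmentPolicy-class].
#' @param seed optional integer overriding `policy@seed`; use a distinct
#'   seed per (image, epoch) draw during training.
#' @param audit if `TRUE`, return `list(image=, audit=)` where `audit` is a
#'   data.frame recording every spec and whether it was applied.
#' @return A [GrayImage-class], or a list when `audit = TRUE`.
#' @examples
#' pol <- AugmentPolicy(list(AugmentSpec("translation", 1, 0.10)), seed = 3)
#' out1 <- applyPolicy(GrayImage(matrix(runif(256), 16, 16)), pol)
#' @export
applyPolicy <- function(img, policy, seed = NULL, audit = FALSE) {
    stopifnot(is(img, "GrayImage"), is(policy, "AugmentPolicy"))
    d <- dim(img)
    if (is.null(seed)) seed <- policy@seed
    plan <- withSeed(seed, .drawPlan(policy, d[1], d[2]))
    out <- .applyPlan(img, plan)
    if (!audit) return(out)
    list(image = out,
         audit = data.frame(
             name = vapply(plan, `[[`, character(1), "name"),
             applied = vapply(plan, `[[`, logical(1), "applied")))
}

#' Apply a policy identically across the channels of a stack
#'
#' Draws one plan (gates, shifts, angles, noise field) and replays it on
#' every channel, so geometric transforms stay aligned across the stack.
#'
#' @param mci a [MultiChannelImage-class].
#' @param policy an [AugmentPolicy-class].
#' @param seed optional integer overriding `policy@seed`.
#' @return A [MultiChannelImage-class].
#' @export
applyPolicyMulti <- function(mci, policy, seed = NULL) {
    stopifnot(is(mci, "MultiChannelImage"), is(policy, "AugmentPolicy"))
    d <- dim(mci)
    if (is.null(seed)) seed <- policy@seed
    plan <- withSeed(seed, .drawPlan(policy, d[1], d[2]))
    MultiChannelImage(lapply(mci@channels, .applyPlan, plan = plan))
}

#' Augmentation policies at the study settings
#'
#' Convenience constructor for single-augmentation policies at the settings
#' used throughout this package's evaluation harness: magnitude-type
#' augmentations (translation 10% of image length, cropping 159 px,
#' rotation 20 degrees, occlusion 5% of area) applied with chance 1 when
#' enabled, and chance-type augmentations (flips, noise, equalisation,
#' sharpening, inversion) gated at the given chance.
#'
#' @param names character vector of augmentation names (see
#'   [AugmentSpec-class]).
#' @param chance application chance for chance-type augmentations
#'   (default 0.10).
#' @param seed policy seed.
#' @return An [AugmentPolicy-class].
#' @examples
#' standardPolicy("translation", seed = 1)
#' @export
standardPolicy <- function(names, chance = 0.10, seed = 0L) {
    magnitudeType <- c("translation", "cropping", "rotation", "occlusion")
    specs <- lapply(names, function(nm) {
        AugmentSpec(nm, chance = if (nm %in% magnitudeType) 1 else chance)
    })
    AugmentPolicy(specs, seed = seed)
}
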