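# internal helpers shared across modules

# coerce Volume3D / PSF3D / plain array to a bare 3-D double array
as_arr <- function(x, what = "volume") {
    if (is(x, "Volume3D")) x <- x@.Data
    if (is.null(dim(x)) || length(dim(x)) != 3L)
        stop(what, " must be a 3-D array (z, y, x)")
    storage.mode(x) <- "double"
    x
}

check_kernel_fits <- function(vdim, kdim) {
    if (any(kdim > vdim))
        stop("kernel dimensions (", paste(kdim, collapse = "x"),
             ") exceed volume dimensions (", paste(vdim, collapse = "x"), ")")
}

# embed a kernel into a volume-sized array with its geometric centre
# floor(size/2) (0-based) wrapped to the origin, ready for FFT convolution
embed_kernel <- function(kern, vdim) {
    kdim <- dim(kern)
    full <- array(0, vdim)
    full[seq_len(kdim[1]), seq_len(kdim[2]), seq_len(kdim[3])] <- kern
    ctr <- kdim %/% 2L                      # 0-based centre index per axis
    idx <- lapply(1:3, function(a)
        ((seq_len(vdim[a]) - 1L + ctr[a]) %% vdim[a]) + 1L)
    full[idx[[1]], idx[[2]], idx[[3]]]
}

# circular convolution given the precomputed FFT of the embedded kernel
cconv_fft <- function(vol, kfft) {
    Re(stats::fft(stats::fft(vol) * kfft, inverse = TRUE)) / length(vol)
}

# root-mean-square error between two equally shaped arrays
rmse <- function(a, b) sqrt(mean((as_arr(a) - as_arr(b))^2))

# run code with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}
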