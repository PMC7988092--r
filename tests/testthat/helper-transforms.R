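# whole-voxel translations and axis mirrors of masks, used by the
# invariance checks

shift_mask <- function(mask, by) {
    v <- array(0L, mask$shape)
    d <- mask$shape
    src <- lapply(1:3, function(a) seq_len(d[a] - abs(by[a])) + max(0L, -by[a]))
    dst <- lapply(1:3, function(a) seq_len(d[a] - abs(by[a])) + max(0L, by[a]))
    v[dst[[1]], dst[[2]], dst[[3]]] <- mask$voxels[src[[1]], src[[2]], src[[3]]]
    out <- mask; out$voxels <- v; out
}

mirror_mask <- function(mask, axis) {
    idx <- lapply(mask$shape, seq_len)
    idx[[axis]] <- rev(idx[[axis]])
    out <- mask
    out$voxels <- mask$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out
}

case_map <- function(case, f) {
    qam_case(f(case$tumor), f(case$ablation),
             if (!is.null(case$liver)) f(case$liver), case_id = case$case_id)
}
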