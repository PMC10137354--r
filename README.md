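# shearfuse

Multimodal medical image fusion in the non-subsampled shearlet transform
(NSST) domain, for co-registered pairs of 2-D grayscale images — the
CT-plus-MRI setting where one modality carries sharp anatomical boundaries
and the other carries soft-tissue texture, and a clinician wants one image
with both.

## The method

Given co-registered images A and B of identical resolution:

1. **Decompose** both with the NSST (default: 1 scale, 8 directions):
   `{L, H_k} = NSST(X)`, one low band plus directional high bands, all at
   full resolution (shift-invariant; perfect reconstruction).
2. **Fuse the low bands** with an activity-driven sparse representation:
   - activity per patch is the modified sum-modified-Laplacian,
     `MSML(p) = Σ_{i,j∈p} |X∗[-1,2,-1]_h| + |X∗[-1,2,-1]_v|`;
   - the joint patch set is split into edge / texture / smooth clusters by
     `TH1 = 0.13·max MSML` and `TH2 = 0.07·max MSML`;
   - each cluster trains a sub-dictionary with online dictionary learning;
     the merged dictionary `D = [D_e, D_t, D_s]` codes every patch with at
     most T = 4 atoms (orthogonal matching pursuit);
   - per position, the code-and-mean pair of the more active source is
     selected (`MSML_A ≥ MSML_B` → A), and the fused band is rebuilt as
     `D·a + m` with overlap averaging.
3. **Fuse the high bands** by directive contrast
   `DL = MSML / |L|` (raw `MSML` where `|L| ≤ ε`): per pixel, the source
   with larger contrast contributes its coefficient in every band —
   selection, never blending.
4. **Invert** the NSST and clip to [0, 1].

The package also provides a fusion-quality metric suite (mutual
information MI(AB,F), standard deviation, edge-preservation QAB/F, spatial
frequency, mean intensity), a deterministic synthetic CT/MRI-like phantom
generator with ground-truth masks, and a command-line interface.

## Worked example

```r
library(shearfuse)

pair <- generate_pair(phantom_spec(seed = 1))   # 128x128 CT-like / MRI-like pair
res  <- fuse(pair, fusion_config(seed = 1), metrics = TRUE)
print(res)
#> fusion_result: 128 x 128; clusters e/t/s = 652/214/1056; clipped 0.000%
#>   MI=4.2288 SD=77.9591 QAB/F=0.6590 SF=43.4177 Mean=81.8006
```

Reading the numbers: of the 1922 joint low-band patches, 652 were
classified as edge, 214 as texture and 1056 as smooth; no pixel needed
clipping after the inverse transform. `QAB/F = 0.659` says about two
thirds of the sources' Sobel edge information (strength and orientation,
weighted by strength) survives into the fused image — self-fusion scores
exactly 1 on this normalized index. `SD`, `SF` and `Mean` are contrast,
sharpness and brightness summaries on the 0–255 scale; `MI` is the summed
joint-histogram information between the fused image and each source, in
bits. Fusing an image with itself reproduces it at 42.5 dB PSNR — the
only loss is the sparse approximation of the low band.

Command-line use (same engine):

```sh
Rscript inst/cli/shearfuse.R synth -o /tmp/demo --size 128 --seed 1
Rscript inst/cli/shearfuse.R fuse /tmp/demo/a.png /tmp/demo/b.png \
    -o /tmp/demo/fused.png --metrics --seed 1
Rscript inst/cli/shearfuse.R metrics /tmp/demo/a.png /tmp/demo/b.png /tmp/demo/fused.png
```

`fuse` writes the image plus a JSON sidecar with the configuration,
cluster sizes and metrics; identical seeds give byte-identical outputs.

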