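---
title: "Simulating spectral Hadamard microscopy: models, parameters and design choices"
author: "HadamardScope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spectral Hadamard microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The method in brief

Coded-illumination (Hadamard) microscopy replaces the confocal pinhole with
arithmetic. A binary code matrix $P \in \{0,1\}^{n\times n}$ is derived from
a Hadamard matrix $H_m$ ($m = n+1$): drop the all-ones border and map
$\pm 1 \to \{1,0\}$ via $(x+1)/2$. Columns of $P$ satisfy

$$p_k \cdot p_r = \begin{cases}(n-1)/2 & k = r\\ (n-3)/4 & k \neq r,\end{cases}$$

so for the working length $n = 19$ the self-term is 9 and every cross-term
is 4. Each illumination cell at 0-based $(i,j)$ is assigned code
$k(i,j) = ((iq + j)\bmod n) + 1$; illuminating with the $n$ patterns and
projecting the recorded temporal signal at each pixel back onto the columns
of $P$ ("decoding") concentrates each code's in-focus signal at its own
cells — the *digital pinholes* — while everything else contributes only the
flat cross-talk offset $(n-3)/4$. Subtracting the offset and masking with
the calibrated pinhole array yields an optically sectioned image; adding a
dispersive element stretches each pinhole into a *digital slit* whose
intensity profile is the local emission spectrum, giving hyperspectral
imaging from the same frame stack.

Because the code construction used here is cyclic, every pattern is a
lattice translation of one master pattern (`selfSimilarityShift()` finds
and verifies the translation exhaustively). A single holographic
metasurface plus a motorized stage can therefore replace a spatial light
modulator; the package designs the corresponding phase mask by
Gerchberg–Saxton iteration and simulates its far field by Fraunhofer
propagation.

# Code construction

For $n$ prime with $n \equiv 3 \pmod 4$, we set
$P[a,b] = 1$ iff $(a+b) \bmod n$ is a non-zero quadratic residue, and embed
$2P - J$ as the core of $H$ under an all-ones border. This reflected
(back-circulant) quadratic-residue core is row-permutation-equivalent to
the textbook circulant construction, but has two advantages that the
circulant core lacks simultaneously: it is *symmetric* (so $P = P^T$ holds
exactly, and decoding with $P$ or $P^T$ is the same operation) and it keeps
the cyclic column structure that gives the patterns their self-similarity.
The orthogonality $HH^T = mI$ and the dot-product identities hold in exact
integer arithmetic and are asserted for every valid order up to 100.

`validOrders()` enumerates the admissible lengths (3, 7, 11, 19, 23, 31,
43, ...). Defaults follow the working configuration $(n, q, \text{cell}) =
(19, 5, 3\,\text{px})$. With it, every pixel is illuminated in $(n-1)/2 =
9$ of the 19 frames per cycle — a 9-fold exposure gain over sequential
single-pinhole illumination — and a full acquisition with 4-fold speckle
averaging takes $19 \times 4 = 76$ frames.

# Forward model

The virtual microscope uses a 10×/NA 0.3 objective, 6.5 µm camera pixels
(0.65 µm effective), a 75× demagnified illumination path at 488 nm, and a
490–700 nm detection band. Three kernels describe the optics:

* **Imaging PSF** — isotropic Gaussian, $\sigma = 0.54$ px, unit sum.
* **Scattering PSF** — Monte Carlo photon transport from an isotropic
  point emitter at 50 µm depth: exponential steps with mean free path
  $1/\mu_s$ ($\mu_s = 100\ \mathrm{cm^{-1}}$), Henyey–Greenstein
  anisotropy $g = 0.9$, continuous absorption weighting
  ($\mu_a = 0.1\ \mathrm{cm^{-1}}$), acceptance within the NA cone at the
  surface. Ballistic (never-scattered) photons are binned at the origin —
  the objective refocuses them onto the emitter's conjugate point — and
  scattered photons at their surface exit position. $g$ and $\mu_a$ are not
  fixed by the physical setup description and are exposed as configuration;
  the defaults are typical for cortical tissue. The kernel is truncated at
  99.9 % cumulative energy and renormalized. The default photon budget is
  $10^6$ (seconds on one CPU, seeded).
* **Spectral PSF** — the imaging kernel translated channel by channel along
  the dispersion direction: channel $c$ of $C$ is displaced by
  $(c-1)/(C-1) \cdot L$ at angle $\theta$, with $L = 40$ px (26 µm) and
  $\theta = -21°$. Angles are measured counter-clockwise from the +x
  (column) axis; $-21°$ points right-and-down in image coordinates, and
  the same convention is used in reconstruction. Sub-pixel shifts use
  bilinear interpolation.

Frame stacks follow the printed forward equations: the calibration stack
is $I_P = O \times (I_H * \mathrm{PSF_{img}})$, the spectral calibration
adds a convolution with the channel-averaged spectral kernel, the tissue
stack is $I_T = [\mathrm{Avg}_c(O_H) \times I_H'] * \mathrm{PSF_{scatter}}$
and the spectral tissue stack modulates each channel of $O_H$, convolves
with its displaced kernel, averages over channels (the monochrome camera
integrates wavelengths) and finally applies the scattering kernel. That
final ordering — scattering after dispersion — follows the printed
equation even though physically scattering precedes the detection prism;
the two convolutions commute in this shift-invariant model, so nothing is
lost. Convolutions are zero-padded "same" (a dark field outside the FOV);
all quantitative test assertions exclude a border band of kernel radius.

# Calibration and offset subtraction

Decoding the ideal pattern stack yields exactly two values, 9 and 4. The
pinhole mask subtracts the offset 4, normalizes by the range
$(n+1)/4 = 5$ and thresholds at 0.5 (Otsu thresholding is available as an
option). For decoded *images* (not the ideal calibration), the offset
generalizes per pixel to $(n-3)/(2(n-1))$ times the temporal sum, which
reduces to $(n-3)/4$ in the calibration case and cancels the cross-talk
term exactly for any unscattered object.

The slit mask thresholds the offset-subtracted decoded spectral
calibration at a fraction of its maximum, default 0.2. The choice is
driven by geometry: the dispersed line ramps up over its first few pixels
and the pinhole sits on that ramp at roughly a quarter of the line
plateau, so any threshold above ~0.25 orphans pinholes from their slits.
A second geometric fact is worth knowing: the same-code cell lattice for
$(n,q) = (19,5)$ contains the offset (3, 4) cells, i.e. a same-code
neighbor 14.4 px ahead along the dispersion direction and only ~4 px off
it laterally. Full-length 40 px slits of one code therefore chain into
connected diagonal runs; this is a property of the code lattice, not of
the threshold. Shorter dispersions (or larger $n$) produce isolated
slits, which is how the per-slit orientation and disjointness properties
are exercised in the tests.

# Reconstruction

* **Wide field**: the frame mean (the cycle sums to uniform
  illumination).
* **Optical sectioning**: decode, subtract the per-pixel offset, mask
  with the pinholes, average over slices, clamp at zero, and smooth with
  a Gaussian of $\sigma$ = one cell (3 px) to suppress the periodic
  pinhole-grid artifact. The filter width is the package's choice; the
  artifact suppression step itself is part of the method.
* **Hyperspectral**: rotate the slit-masked decoded stack (bilinear) and
  the pinhole mask (nearest-neighbor, preserving binarity) by $+21°$
  about the frame center so dispersion lies along +x, read the $C$-pixel
  horizontal profile starting at every pinhole pixel as that pixel's
  spectrum (weighted by the rotated mask), and sum over code slices.
  Reading per pinhole pixel follows the printed recipe literally; the
  3 px pinhole therefore assigns nearly identical spectra (shifted by at
  most one channel) to its pixels, consistent with spectral sampling
  being limited by pinhole size. Pinholes whose profile would leave the
  rotated frame are skipped by default (after rotation the frame edge
  always clips some profiles; an `edge = "error"` mode is available).
  The accumulated cube is de-rotated back to the original frame — so it
  is directly comparable with the ground truth and with the sectioned
  image — and smoothed channel-wise. Channel 1 is the shortest
  wavelength at zero displacement; the dispersion sign is configurable
  since it is hardware-dependent.

The channel count is matched to the dispersion length (40 channels over
40 px ≈ 1 px per channel) so that the unit-step profile read samples each
channel at its displacement; widely different $C$ and $L$ distort the
recovered spectral axis.

# Synthetic data

`makePhantom()` draws disk-shaped nuclei, random-walk filaments and
ramified blobs into four channels — the structural classes of a
multi-marker stained tissue section — with seeded reproducibility.
`dyeSpectra()` provides four unimodal red-skewed emission curves spread
over 490–700 nm, row-normalized; they are parameterized stand-ins (peaks
505/545/600/665 nm, chosen to mimic a DAPI + three-Alexa panel clipped at
the 490 nm filter edge), and a CSV loader accepts measured spectra. The
ground truth cube is the exact linear mix $O_H = I_R \circ F$.

What the generator does *not* emulate: realistic organoid morphology,
out-of-focus fluorescence from other axial planes, autofluorescence,
photobleaching, or camera gain/read noise (Poisson shot noise is available
but off by default). Passing tests therefore demonstrate the internal
consistency and the combinatorial/optical properties of the method on
plane objects under the stated kernels — not performance on real tissue
volumes.

# Numerical choices

* FFT-based zero-padded convolution; kernel FFTs are cached per channel.
* GS phase retrieval: unit amplitude inside the circular aperture, seeded
  uniform random initial phase, 100 iterations by default (the iteration
  count, initialization and speckle shift offsets are not fixed by the
  physical description and are exposed as configuration); the
  Fourier-magnitude RMS error sequence is monotone non-increasing and is
  asserted per iteration. Propagation uses the unitary centered DFT, so
  Parseval holds to 1e-10 relative.
* Speckle averaging translates the far field by full pattern periods
  ($n \cdot \text{cell} = 57$ px); shifts wrap circularly, so hologram
  targets are generated at period-multiple frame sizes (342 px default,
  which also accommodates the 303-atom aperture of a 100 µm / 330 nm
  metasurface). Non-preserving shifts are rejected.
* Rotation uses one shared center convention for bilinear intensities and
  nearest-neighbor masks, keeping the projection and the mask registered;
  de-rotation returns pinhole positions to within 1 px.
* Monte Carlo transport is vectorized over photons; degenerate directions
  near ±z use the standard special-case update. Free-path sampling is
  exposed (`sampleFreePaths()`) so its exponential moments can be checked
  directly.

# Problem sizes

The default end-to-end configuration is a 256 × 256 px frame, $n = 19$,
$C = 40$ channels and $10^6$ Monte Carlo photons; a full `runPipeline()`
takes well under a minute on one CPU. Unit tests run the shared scene at
128 × 128 px and the Monte Carlo checks at 0.5–2 × 10^5 photons; these
sizes were chosen so the whole suite stays interactive while every
property remains measurable.

# Known limitations

* With the stated scattering parameters ($\mu_s d = 0.5$), roughly half
  of the collected light is ballistic and refocused sharply, so the
  simulated wide-field image retains most fine structure; global
  correlation with the ground truth does not rank the sectioned image
  above the wide-field image, even though the background-suppression
  ratio (the sectioned image's normalized background energy over the
  wide-field's) shows strong scattering rejection. Severely blurred
  wide-field imaging requires $\mu_s d \gg 1$.
* Wavelengths are index-labeled on a linear nm axis; absolute wavelength
  calibration would need a multi-band reference sample.
* The meta-atom lookup (`snapToMetaAtoms()`) snaps phases to a supplied
  library table; no electromagnetic solver is included.
* Spectral unmixing of the recovered cube into dye abundances is provided
  only for the ground-truth cube (`unmixAbundances()`); deconvolution and
  sub-cell spectral interpolation are out of scope.
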