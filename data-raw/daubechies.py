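"""Compute Daubechies orthonormal scaling filters by spectral factorization.

For order N the lowpass filter h has 2N taps. Construction: find the roots of
P(y) = sum_{k=0}^{N-1} C(N-1+k, k) y^k, map each root y to the z-domain via
z^2 - (2 - 4y) z + 1 = 0, keep the root inside the unit circle, and form
h(z) = c * ((1+z)/2)^N * prod (z - z_i), normalized so sum h = sqrt(2).
All arithmetic in mpmath at 120 significant digits; the minimum-phase root
choice reproduces the conventional (PyWavelets/MATLAB) filters.
"""
import mpmath as mp

mp.mp.dps = 120

def daub(N):
    # P(y) coefficients, highest degree first for polyroots
    coeffs = [mp.binomial(N - 1 + k, k) for k in range(N)]
    roots = mp.polyroots(list(reversed(coeffs)), maxsteps=200, extraprec=400)
    zroots = []
    for y in roots:
        # z^2 - (2 - 4y) z + 1 = 0
        b = 2 - 4 * y
        disc = mp.sqrt(b * b - 4)
        z1 = (b + disc) / 2
        z2 = (b - disc) / 2
        z = z1 if abs(z1) < 1 else z2
        zroots.append(z)
    # h(z) = c (1+z)^N prod(z - z_i); build polynomial coefficients
    poly = [mp.mpf(1)]
    for _ in range(N):  # multiply by (1+z)
        poly = [a + b for a, b in zip(poly + [mp.mpf(0)], [mp.mpf(0)] + poly)]
    for z0 in zroots:   # multiply by (z - z0)
        poly = [a - z0 * b for a, b in zip([mp.mpf(0)] + poly, poly + [mp.mpf(0)])]
    # keep real part (imaginary residue ~ 0), normalize sum to sqrt(2)
    h = [mp.re(c) for c in poly]
    s = sum(h)
    h = [c / s * mp.sqrt(2) for c in h]
    # conventional orientation: largest taps near the start (min-phase)
    n = len(h)
    if sum(abs(c) for c in h[: n // 2]) < sum(abs(c) for c in h[n // 2 :]):
        h = h[::-1]
    return h

orders = [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 15, 20, 25, 30, 35, 40, 45]
with open("/root/pkg/inst/extdata/daubechies_filters.csv", "w") as f:
    f.write("order,tap,h\n")
    for N in orders:
        h = daub(N)
        assert len(h) == 2 * N
        # orthonormality checks at high precision
        e = sum(c * c for c in h)
        assert abs(e - 1) < mp.mpf("1e-80"), (N, e)
        for k in range(1, N):
            d = sum(h[i] * h[i + 2 * k] for i in range(2 * N - 2 * k))
            assert abs(d) < mp.mpf("1e-80"), (N, k, d)
        for t, c in enumerate(h):
            f.write(f"{N},{t},{mp.nstr(c, 18, strip_zeros=False)}\n")
print("written")
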