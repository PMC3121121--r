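"""Delaunay edge extraction: reads whitespace-separated 3D points, writes the
unique 1-based vertex pairs that share a tetrahedron (i.e. a Voronoi facet)."""
import sys

import numpy as np
from scipy.spatial import Delaunay


def main(infile, outfile):
    pts = np.loadtxt(infile, ndmin=2)
    tri = Delaunay(pts)
    s = tri.simplices
    pairs = []
    m = s.shape[1]
    for a in range(m):
        for b in range(a + 1, m):
            pairs.append(np.stack([s[:, a], s[:, b]], axis=1))
    e = np.concatenate(pairs)
    e.sort(axis=1)
    e = np.unique(e, axis=0) + 1
    np.savetxt(outfile, e, fmt="%d")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
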