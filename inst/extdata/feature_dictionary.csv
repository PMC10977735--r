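feature,group,unit,aggregation,definition
Cell_Area,Size,px,per-cell,Total number of pixels occupied by the cell mask
Cell_MeanIntensity,Density & Texture,intensity,per-cell,Mean cell-channel intensity over the cell mask
Cell_MaxIntensity,Density & Texture,intensity,per-cell,Maximum cell-channel intensity over the cell mask
Cell_Perimeter,Size,px,per-cell,Boundary contour length of the cell mask with diagonal-step correction
Cell_Compaction,Shape,unitless,per-cell,Minor/major axis ratio of the cell's moment-equivalent ellipse (in (0 and 1])
Cell_Roundness,Shape,unitless,per-cell,sqrt(4*Area/pi)/(Perimeter/pi); 1 for a perfect circle
MitoCluster_Fractal2,Connectivity,unitless,per-cell union mask,Box-counting fractal dimension at box size 4 px
MitoCluster_Fractal8,Connectivity,unitless,per-cell union mask,Box-counting fractal dimension at box size 16 px
MitoCluster_Fractal32,Connectivity,unitless,per-cell union mask,Box-counting fractal dimension at box size 64 px
MitoCluster_Count,Abundance,count,count,Number of mitochondrial clusters in the cell
MitoCluster_Area,Size,px,sum over clusters,Summed cluster pixel areas
MitoCluster_Elongation,Shape,unitless,mean over clusters,Major/minor axis ratio of the cluster ellipse (>= 1)
MitoCluster_Compaction,Shape,unitless,mean over clusters,Minor/major axis ratio of the cluster ellipse
MitoCluster_Roundness,Shape,unitless,mean over clusters,sqrt(4*Area/pi)/(Perimeter/pi) per cluster
MitoCluster_EulerNumber,Connectivity,unitless,mean over clusters,Components minus holes per cluster (1 solid; 0 annulus)
Mito_MeanIntensity,Density & Texture,intensity,per-cell union mask,Mean mitochondrial-channel intensity over cluster support
Mito_MaxIntensity,Density & Texture,intensity,mean over clusters,Mean of per-cluster maximum mitochondrial intensity
MitoCluster_Perimeter,Size,px,mean over clusters,Mean cluster boundary contour length
MitoCluster_Solidity,Density & Texture,unitless,mean over clusters,Convex-hull perimeter divided by object perimeter (a perimeter ratio)
Skel_Width,Size,px,per-cell,Total cluster area divided by total skeleton length (mean tubule width proxy)
Skel_Length,Size,px,sum over branches,Summed geodesic skeleton branch length
Skel_BranchPointsCount,Connectivity,count,per-cell,Number of merged skeleton junction nodes
Skel_EndPointsCount,Connectivity,count,per-cell,Number of skeleton end-point pixels
Skel_BranchPointsEndPointsRatio,Connectivity,unitless,per-cell,Branch points / (branch points + end points); 0 when both are 0
Mito_Compaction,Shape,unitless,mean over isolated mitochondria,Minor/major axis ratio of each isolated mitochondrion
Mito_Elongation,Shape,unitless,mean over isolated mitochondria,Major/minor axis ratio of each isolated mitochondrion
Mito_Roundness,Shape,unitless,mean over isolated mitochondria,sqrt(4*Area/pi)/(Perimeter/pi) per isolated mitochondrion
Mito_Length,Size,px,sum over isolated mitochondria,Summed skeleton-branch length of isolated mitochondria
DistToMembrane,Density & Texture,px,mean over skeleton pixels,Euclidean distance from skeleton pixels to the cell boundary
DistToNuclei,Density & Texture,px,mean over skeleton pixels,Euclidean distance from skeleton pixels to the nuclear envelope
RatioDistMemb0Nucl1,Density & Texture,unitless,mean over skeleton pixels,DistToNuclei/(DistToMembrane+DistToNuclei) per pixel; 0 at the nucleus and 1 at the membrane
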