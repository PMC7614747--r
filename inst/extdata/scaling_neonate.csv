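tissue,freq_MHz,ratio_eps,ratio_sigma,source
skin,297,1.20,1.45,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
fat,297,1.45,1.75,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
muscle,297,1.14,1.35,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
bone,297,1.40,1.70,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
brain,297,1.18,1.30,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
csf,297,1.00,1.02,synthetic default: already high-water tissue; near-unity ratio
blood,297,1.02,1.05,synthetic default: already high-water tissue; near-unity ratio
heart,297,1.12,1.30,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
lung,297,1.10,1.25,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
liver,297,1.15,1.35,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
cartilage,297,1.20,1.40,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
connective,297,1.25,1.50,synthetic default: water-content-motivated newborn/adult ratio; supply authoritative ratios for publication use
eye,297,1.00,1.02,synthetic default: already high-water tissue; near-unity ratio
blanket_wool,297,1.00,1.00,identity: insulation layer is not age-scaled
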