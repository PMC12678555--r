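category,trophic_class,c_D,c_E
ungulates,animal_vertebrate,0.9,2
small_mammals,animal_vertebrate,0.9,2
carrion,animal_vertebrate,0.9,2
fish,animal_vertebrate,0.9,2.2
birds,animal_vertebrate,0.9,2
herptiles,animal_vertebrate,0.9,1.8
social_insects,animal_invertebrate,0.8,1.6
other_insects,animal_invertebrate,0.8,1.6
other_invertebrates,animal_invertebrate,0.8,1.5
fleshy_fruits,plant,0.65,1
hard_mast,plant,0.7,1.5
seeds,plant,0.7,1.4
graminoids,plant,0.3,0.8
forbs,plant,0.35,0.8
browse_foliage,plant,0.3,0.8
roots_tubers,plant,0.55,1
bamboo,plant,0.25,0.7
crops,plant,0.75,1.3
fungi,fungi,0.45,0.7
other_debris,other,0.3,0.5
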