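plant_species	plant_order
Fabales_plant01	Fabales
Fabales_plant02	Fabales
Fabales_plant03	Fabales
Fabales_plant04	Fabales
Fabales_plant05	Fabales
Fabales_plant06	Fabales
Fabales_plant07	Fabales
Fabales_plant08	Fabales
Rosales_plant01	Rosales
Rosales_plant02	Rosales
Rosales_plant03	Rosales
Rosales_plant04	Rosales
Rosales_plant05	Rosales
Rosales_plant06	Rosales
Rosales_plant07	Rosales
Rosales_plant08	Rosales
Malpighiales_plant01	Malpighiales
Malpighiales_plant02	Malpighiales
Malpighiales_plant03	Malpighiales
Malpighiales_plant04	Malpighiales
Malpighiales_plant05	Malpighiales
Malpighiales_plant06	Malpighiales
Malpighiales_plant07	Malpighiales
Malpighiales_plant08	Malpighiales
Asterales_plant01	Asterales
Asterales_plant02	Asterales
Asterales_plant03	Asterales
Asterales_plant04	Asterales
Asterales_plant05	Asterales
Asterales_plant06	Asterales
Asterales_plant07	Asterales
Asterales_plant08	Asterales
Poales_plant01	Poales
Poales_plant02	Poales
Poales_plant03	Poales
Poales_plant04	Poales
Poales_plant05	Poales
Poales_plant06	Poales
Poales_plant07	Poales
Poales_plant08	Poales
Lamiales_plant01	Lamiales
Lamiales_plant02	Lamiales
Lamiales_plant03	Lamiales
Lamiales_plant04	Lamiales
Lamiales_plant05	Lamiales
Lamiales_plant06	Lamiales
Lamiales_plant07	Lamiales
Lamiales_plant08	Lamiales
Sapindales_plant01	Sapindales
Sapindales_plant02	Sapindales
Sapindales_plant03	Sapindales
Sapindales_plant04	Sapindales
Sapindales_plant05	Sapindales
Sapindales_plant06	Sapindales
Sapindales_plant07	Sapindales
Sapindales_plant08	Sapindales
Myrtales_plant01	Myrtales
Myrtales_plant02	Myrtales
Myrtales_plant03	Myrtales
Myrtales_plant04	Myrtales
Myrtales_plant05	Myrtales
Myrtales_plant06	Myrtales
Myrtales_plant07	Myrtales
Myrtales_plant08	Myrtales
Ericales_plant01	Ericales
Ericales_plant02	Ericales
Ericales_plant03	Ericales
Ericales_plant04	Ericales
Ericales_plant05	Ericales
Ericales_plant06	Ericales
Ericales_plant07	Ericales
Ericales_plant08	Ericales
Gentianales_plant01	Gentianales
Gentianales_plant02	Gentianales
Gentianales_plant03	Gentianales
Gentianales_plant04	Gentianales
Gentianales_plant05	Gentianales
Gentianales_plant06	Gentianales
Gentianales_plant07	Gentianales
Gentianales_plant08	Gentianales
Fagales_plant01	Fagales
Fagales_plant02	Fagales
Fagales_plant03	Fagales
Fagales_plant04	Fagales
Fagales_plant05	Fagales
Fagales_plant06	Fagales
Fagales_plant07	Fagales
Fagales_plant08	Fagales
Pinales_plant01	Pinales
Pinales_plant02	Pinales
Pinales_plant03	Pinales
Pinales_plant04	Pinales
Pinales_plant05	Pinales
Pinales_plant06	Pinales
Pinales_plant07	Pinales
Pinales_plant08	Pinales
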